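# Independent oracles used across test files.

# Naive agglomerative furthest-neighbour clustering: repeatedly merge the
# two clusters with the smallest complete-linkage distance while that
# distance stays at or below the threshold. Ties broken by lexicographic
# order of the smallest member labels. O(n^3), independent of hclust.
naive_complete_linkage <- function(d, threshold) {
  ids <- rownames(d)
  clusters <- as.list(ids)
  repeat {
    if (length(clusters) == 1) break
    best <- NULL
    best_dist <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        cl_dist <- max(d[clusters[[i]], clusters[[j]], drop = FALSE])
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        if (cl_dist < best_dist ||
            (cl_dist == best_dist &&
             paste(key, collapse = "\r") <
             paste(sort(c(min(clusters[[best[1]]]), min(clusters[[best[2]]]))),
                   collapse = "\r"))) {
          best <- c(j, i)
          best_dist <- cl_dist
        }
      }
    }
    if (best_dist > threshold) break
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  # partition as a canonical label map: member -> smallest member label
  out <- character(0)
  for (cl in clusters) out[cl] <- sort(cl)[1]
  out[ids]
}

random_distance_matrix <- function(n) {
  d <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
  d[lower.tri(d)] <- runif(n * (n - 1) / 2)
  d + t(d)
}

# Forward closed form for an exponentially decaying consumption rate with a
# Dirichlet top and zero-gradient bottom (diffusion + reaction only):
#   D C'' = R0 exp(-x / lambda) / 1000   (mM d^-1), C(0)=C0, C'(L)=0
closed_form_exp_rate <- function(x, C0, D_cm2_d, R0_nmol, lambda, L) {
  r0 <- R0_nmol / 1000
  c1 <- (r0 * lambda / D_cm2_d) * exp(-L / lambda)
  C0 - (r0 * lambda^2 / D_cm2_d) + (r0 * lambda^2 / D_cm2_d) * exp(-x / lambda) + c1 * x
}
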