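#' Pairwise p-distances from an alignment with pairwise gap exclusion
#'
#' For each pair of aligned sequences, the distance is the fraction of
#' mismatching sites among sites where both sequences carry an unambiguous
#' base (`A`, `C`, `G`, `T` or `U`). Sites with a gap or an ambiguity code
#' in either sequence are excluded from numerator and denominator (pairwise
#' deletion).
#'
#' @param alignment Named character vector of equal-length aligned sequences
#'   (e.g. from [read_alignment_fasta()]).
#' @return A symmetric numeric matrix of p-distances in `[0, 1]` with
#'   sequence ids as dimnames.
#' @export
#' @examples
#' pairwise_pdistance(c(a = "ACGT", b = "ACGA", c = "AC-T"))
pairwise_pdistance <- function(alignment) {
  if (is.null(names(alignment)) || any(!nzchar(names(alignment)))) {
    seep_abort("alignment sequences must be named", "seep_validation_error")
  }
  lens <- nchar(alignment)
  if (length(unique(lens)) > 1) {
    seep_abort("sequences must have equal (aligned) length",
               "seep_alignment_error")
  }
  n <- length(alignment)
  ids <- names(alignment)
  chars <- do.call(rbind, strsplit(toupper(alignment), ""))
  valid <- matrix(chars %in% c("A", "C", "G", "T", "U"), nrow = n)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(if (i > 1) i - 1 else 0)) {
      ok <- valid[i, ] & valid[j, ]
      n_sites <- sum(ok)
      if (n_sites == 0) {
        seep_abort(sprintf("no comparable sites between '%s' and '%s'",
                           ids[i], ids[j]), "seep_distance_error")
      }
      d[i, j] <- d[j, i] <- sum(chars[i, ok] != chars[j, ok]) / n_sites
    }
  }
  d
}

#' Cluster sequences into OTUs by furthest-neighbour linkage
#'
#' Agglomerative complete-linkage (furthest-neighbour) clustering of a
#' pairwise distance matrix, cut at a distance threshold: two clusters merge
#' only while the maximum distance between any cross pair does not exceed
#' the threshold, so every OTU is guaranteed a maximum intra-OTU distance at
#' or below the cutoff. A similarity level maps to the threshold as
#' `d = 1 - s` (98% similarity -> 0.02). OTU ids are named after the
#' lexicographically smallest member.
#'
#' @param d Symmetric distance matrix with labels (see
#'   [read_distance_matrix()] or [pairwise_pdistance()]).
#' @param threshold Distance cutoff in `[0, 1]`.
#' @return An `otu_clustering` object: list with `assignments` (tibble
#'   `sequence_id`, `otu_id`), `sizes` (tibble `otu_id`, `size`) and
#'   `threshold`.
#' @export
#' @examples
#' d <- pairwise_pdistance(c(a = "ACGTACGT", b = "ACGTACGA", c = "TTTTACGG"))
#' cluster_otus(d, threshold = 0.2)
cluster_otus <- function(d, threshold) {
  d <- validate_distance_matrix(d)
  if (threshold < 0 || threshold > 1) {
    seep_abort("threshold must lie in [0, 1]", "seep_domain_error")
  }
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(d)))
  if (nrow(d) == 1) {
    cl <- setNames(1L, ids)
  } else {
    hc <- hclust(as.dist(d), method = "complete")
    cl <- cutree(hc, h = threshold)
    names(cl) <- ids
  }
  # canonical OTU id: smallest member label
  rep_label <- vapply(split(ids, cl), function(x) sort(x)[1], character(1))
  assignments <- tibble::tibble(sequence_id = ids,
                                otu_id = unname(rep_label[as.character(cl)])) |>
    dplyr::arrange(.data$otu_id, .data$sequence_id)
  sizes <- dplyr::count(assignments, .data$otu_id, name = "size")
  structure(list(assignments = assignments, sizes = sizes,
                 threshold = threshold, linkage = "complete"),
            class = "otu_clustering")
}

#' @export
print.otu_clustering <- function(x, ...) {
  cat(sprintf("<otu_clustering> %d sequences in %d OTUs (complete linkage, distance cutoff %g)\n",
              nrow(x$assignments), nrow(x$sizes), x$threshold))
  print(x$sizes)
  invisible(x)
}

#' Bias-corrected Chao1 richness estimate
#'
#' Nonparametric richness estimator extrapolating unseen taxa from the
#' singleton and doubleton counts, in the bias-corrected form
#' \deqn{S_{Chao1} = S_{obs} + \frac{n_1 (n_1 - 1)}{2 (n_2 + 1)},}
#' where \eqn{n_1} and \eqn{n_2} are the numbers of OTUs observed exactly
#' once and exactly twice. The correction vanishes when \eqn{n_1 \le 1}, and
#' the estimate never falls below the observed richness.
#'
#' @param sizes OTU abundances: a numeric vector of sizes (all >= 1), or an
#'   `otu_clustering` object.
#' @return One-row tibble: `s_obs`, `n1`, `n2`, `s_chao1`, `sample_size`.
#' @export
#' @examples
#' chao1(c(1, 1, 1, 1, 2, 2, 3, 5, 9, 10))
chao1 <- function(sizes) {
  if (inherits(sizes, "otu_clustering")) sizes <- sizes$sizes$size
  if (length(sizes) == 0) {
    seep_abort("empty OTU size multiset", "seep_validation_error")
  }
  if (any(sizes < 1) || any(sizes != round(sizes))) {
    seep_abort("OTU sizes must be positive integers", "seep_validation_error")
  }
  s_obs <- length(sizes)
  n1 <- sum(sizes == 1)
  n2 <- sum(sizes == 2)
  tibble::tibble(s_obs = s_obs, n1 = n1, n2 = n2,
                 s_chao1 = s_obs + n1 * (n1 - 1) / (2 * (n2 + 1)),
                 sample_size = sum(sizes))
}

#' Clone-library size quality control
#'
#' Flags libraries whose size deviates from the mean library size by 20% or
#' more of their own total:
#' `deviation_i = |size_i - mean(sizes)| / size_i`, pass iff
#' `deviation_i < 0.20`. When a `domain` grouping is supplied (bacteria vs.
#' archaea), the mean is taken within each domain.
#'
#' @param sizes Named numeric vector of library sizes, or a data frame with
#'   `sample_id` and `size` (and optionally `domain`) columns.
#' @param max_deviation Deviation threshold (default 0.20, strict `<`).
#' @return Tibble with per-sample deviation and `pass` flag.
#' @export
#' @examples
#' library_size_qc(c(MatB_0_3 = 62, Edge_0_3 = 41, Out_0_3 = 55))
library_size_qc <- function(sizes, max_deviation = 0.20) {
  if (!is.data.frame(sizes)) {
    sizes <- tibble::tibble(sample_id = names(sizes), size = as.numeric(sizes))
  }
  sizes <- tibble::as_tibble(sizes)
  if (!all(c("sample_id", "size") %in% names(sizes))) {
    seep_abort("need columns sample_id and size", "seep_format_error")
  }
  if (nrow(sizes) < 2) {
    seep_abort("at least two libraries are required", "seep_validation_error")
  }
  if (any(sizes$size <= 0)) {
    seep_abort("library sizes must be positive", "seep_validation_error")
  }
  grouping <- if ("domain" %in% names(sizes)) "domain" else character(0)
  sizes |>
    dplyr::mutate(mean_size = mean(.data$size),
                  deviation = abs(.data$size - .data$mean_size) / .data$size,
                  pass = .data$deviation < max_deviation,
                  .by = dplyr::all_of(grouping))
}
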