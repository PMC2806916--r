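#' Read a depth-interval profile table
#'
#' Profile tables hold depth-resolved porewater observations for one or more
#' sediment cores: solute concentrations (mM), volumetric process rates
#' (nmol cm\eqn{^{-3}} d\eqn{^{-1}}) or methane \eqn{\delta^{13}}C values
#' (permil), recorded over core sectioning intervals (typically 3 cm).
#' Depths are centimetres below the sediment--water interface, positive
#' downward; intervals are half-open \code{[top, bottom)}.
#'
#' @param path Path to a delimited text file with header columns
#'   \code{core_id}, \code{variable}, \code{depth_top_cm},
#'   \code{depth_bottom_cm}, \code{value} and optionally \code{replicate}.
#' @param dialect `"tsv"` (default) or `"csv"`.
#'
#' @return A validated tibble sorted by core, variable, replicate and depth,
#'   with a `depth_mid_cm` column (arithmetic midpoint of the interval).
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "core_id\tvariable\tdepth_top_cm\tdepth_bottom_cm\tvalue\treplicate",
#'   "MatB\tsulfate\t0\t3\t26.1\t1",
#'   "MatB\tsulfate\t3\t6\t12.4\t1"), f)
#' read_profile_table(f)
read_profile_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    seep_abort(paste0("profile table not found: ", path), "seep_io_error")
  }
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(path, show_col_types = FALSE, progress = FALSE)
  validate_profile_table(raw)
}

#' Validate a profile table
#'
#' Checks the column contract and the depth-interval invariants: every row
#' has `depth_top_cm < depth_bottom_cm`, intervals within one
#' (core, variable, replicate) series do not overlap, and sulfate/methane
#' concentrations are non-negative.
#'
#' @param x A data frame of profile observations.
#' @return The validated tibble, depth-sorted, with `depth_mid_cm` added.
#' @export
validate_profile_table <- function(x) {
  required <- c("core_id", "variable", "depth_top_cm", "depth_bottom_cm", "value")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    seep_abort(
      paste0("profile table is missing column(s): ", paste(missing, collapse = ", ")),
      "seep_format_error"
    )
  }
  x <- tibble::as_tibble(x)
  if (!"replicate" %in% names(x)) x$replicate <- 1L
  x$replicate <- dplyr::coalesce(as.integer(x$replicate), 1L)

  known <- c("sulfate", "methane", "rate_srr", "rate_aom", "d13C")
  bad_var <- setdiff(unique(x$variable), known)
  if (length(bad_var) > 0) {
    seep_abort(
      paste0("unknown variable(s): ", paste(bad_var, collapse = ", "),
             " (expected one of ", paste(known, collapse = ", "), ")"),
      "seep_validation_error"
    )
  }
  if (any(x$depth_top_cm < 0)) {
    seep_abort("depth_top_cm must be non-negative", "seep_validation_error")
  }
  if (any(x$depth_top_cm >= x$depth_bottom_cm)) {
    bad <- which(x$depth_top_cm >= x$depth_bottom_cm)
    seep_abort(
      paste0("depth_top_cm must be < depth_bottom_cm (rows ",
             paste(bad, collapse = ", "), ")"),
      "seep_validation_error"
    )
  }
  conc <- x$variable %in% c("sulfate", "methane")
  if (any(conc & x$value < 0, na.rm = TRUE)) {
    seep_abort("sulfate/methane concentrations must be >= 0",
               "seep_validation_error")
  }

  x <- dplyr::arrange(x, .data$core_id, .data$variable, .data$replicate,
                      .data$depth_top_cm)
  overlaps <- x |>
    dplyr::group_by(.data$core_id, .data$variable, .data$replicate) |>
    dplyr::filter(dplyr::row_number() > 1,
                  .data$depth_top_cm < dplyr::lag(.data$depth_bottom_cm)) |>
    dplyr::ungroup()
  if (nrow(overlaps) > 0) {
    desc <- paste(sprintf("%s/%s rep %d [%g, %g)", overlaps$core_id,
                          overlaps$variable, overlaps$replicate,
                          overlaps$depth_top_cm, overlaps$depth_bottom_cm),
                  collapse = "; ")
    seep_abort(paste0("overlapping depth intervals: ", desc),
               "seep_validation_error")
  }
  x$depth_mid_cm <- (x$depth_top_cm + x$depth_bottom_cm) / 2
  dplyr::relocate(x, "core_id", "variable", "depth_top_cm", "depth_bottom_cm",
                  "depth_mid_cm", "value", "replicate")
}

#' Write a profile table
#'
#' Writes tab- or comma-separated text that [read_profile_table()] reads back
#' exactly (numbers are written in shortest round-trip decimal form). The
#' derived `depth_mid_cm` column is not written.
#'
#' @param x A valid profile table.
#' @inheritParams read_profile_table
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (nrow(x) > 0) x <- validate_profile_table(x)
  cols <- c("core_id", "variable", "depth_top_cm", "depth_bottom_cm",
            "value", "replicate")
  x <- x[, intersect(cols, names(x)), drop = FALSE]
  writer <- if (dialect == "tsv") readr::write_tsv else readr::write_csv
  writer(x, path, progress = FALSE)
  invisible(path)
}

#' Read a PHYLIP-format pairwise distance matrix
#'
#' Accepts the square and the lower-triangle PHYLIP dialects (first line: the
#' number of taxa; then one row per taxon starting with its label). Distances
#' must lie in \code{[0, 1]} (p-distances); a square matrix must be symmetric
#' to within `1e-9` and have a zero diagonal. Lower-triangle input is
#' mirrored to a full symmetric matrix.
#'
#' @param path Path to the distance file.
#' @return A symmetric numeric matrix with taxon labels on both dimnames.
#' @export
read_distance_matrix <- function(path) {
  if (!file.exists(path)) {
    seep_abort(paste0("distance matrix not found: ", path), "seep_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) {
    seep_abort("first line must give the number of taxa", "seep_format_error")
  }
  if (length(lines) != n + 1) {
    seep_abort(sprintf("expected %d taxon rows, found %d", n, length(lines) - 1),
               "seep_format_error")
  }
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "[ \t]+")[[1]])
  labels <- vapply(rows, `[`, character(1), 1)
  vals <- lapply(rows, function(r) suppressWarnings(as.numeric(r[-1])))
  lens <- lengths(vals)

  if (all(lens == n)) {
    d <- do.call(rbind, vals)
  } else if (all(lens == seq_len(n) - 1)) {
    d <- matrix(0, n, n)
    for (i in seq_len(n)) {
      if (i > 1) {
        d[i, seq_len(i - 1)] <- vals[[i]]
        d[seq_len(i - 1), i] <- vals[[i]]
      }
    }
  } else {
    seep_abort("rows match neither the square nor the lower-triangle dialect",
               "seep_format_error")
  }
  if (anyNA(d)) {
    seep_abort("non-numeric distance entry", "seep_format_error")
  }
  dimnames(d) <- list(labels, labels)
  validate_distance_matrix(d)
}

#' Validate a pairwise distance matrix
#'
#' @param d A square numeric matrix of distances in `[0, 1]`.
#' @param tol Symmetry tolerance.
#' @return The matrix, with the diagonal forced to exact zero.
#' @export
validate_distance_matrix <- function(d, tol = 1e-9) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    seep_abort("distance matrix must be square", "seep_validation_error")
  }
  if (any(d < 0 | d > 1)) {
    seep_abort("distances must lie in [0, 1]", "seep_validation_error")
  }
  if (max(abs(d - t(d))) > tol) {
    seep_abort(sprintf("matrix asymmetric beyond %g", tol),
               "seep_validation_error")
  }
  if (any(abs(diag(d)) > tol)) {
    seep_abort("diagonal must be zero", "seep_validation_error")
  }
  diag(d) <- 0
  d
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param d Symmetric distance matrix with labels.
#' @param path Output path.
#' @param digits Significant digits to print (default preserves typical
#'   p-distance precision).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path, digits = 10) {
  d <- validate_distance_matrix(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(c(rownames(d)[i],
                       formatC(d[i, ], digits = digits, format = "g")),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' Records must all have equal length (a multiple alignment) and unique
#' identifiers. Residues are uppercased; gap characters (`-`) are preserved
#' so that downstream pairwise distances can apply gap exclusion.
#'
#' @param path Path to an aligned FASTA file.
#' @return A named character vector of aligned sequences.
#' @export
read_alignment_fasta <- function(path) {
  if (!file.exists(path)) {
    seep_abort(paste0("FASTA not found: ", path), "seep_io_error")
  }
  recs <- ape::read.FASTA(path)
  seqs <- toupper(vapply(as.character(recs), paste, character(1), collapse = ""))
  ids <- names(seqs)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    seep_abort(paste0("duplicate sequence id(s): ",
                      paste(unique(dup), collapse = ", ")),
               "seep_alignment_error")
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    mode_len <- as.integer(names(which.max(table(lens))))
    off <- ids[lens != mode_len]
    seep_abort(paste0("sequences are not aligned (unequal lengths): ",
                      paste(off, collapse = ", ")),
               "seep_alignment_error")
  }
  seqs
}

#' Read and validate a sample-by-taxon count table
#'
#' @param path Delimited file with columns `sample_id`, `taxon_id`, `count`.
#' @inheritParams read_profile_table
#' @return A validated tibble.
#' @export
read_count_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  validate_count_table(reader(path, show_col_types = FALSE, progress = FALSE))
}

#' @rdname read_count_table
#' @param x A data frame of counts.
#' @export
validate_count_table <- function(x) {
  required <- c("sample_id", "taxon_id", "count")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    seep_abort(paste0("count table is missing column(s): ",
                      paste(missing, collapse = ", ")), "seep_format_error")
  }
  x <- tibble::as_tibble(x)
  if (any(x$count < 0) || any(x$count != round(x$count))) {
    seep_abort("counts must be non-negative integers", "seep_validation_error")
  }
  x$count <- as.integer(x$count)
  totals <- x |> dplyr::summarise(n = sum(.data$count), .by = "sample_id")
  if (any(totals$n == 0)) {
    seep_abort(paste0("sample(s) with no positive counts: ",
                      paste(totals$sample_id[totals$n == 0], collapse = ", ")),
               "seep_validation_error")
  }
  x
}

#' Read and validate a taxon-to-role group map
#'
#' Maps taxa (phylotype groups such as Eel-2, SEEP-SRB1, ANME-2a) to an
#' ecological role: `SRB` (sulfate-reducing bacteria), `ANME` (anaerobic
#' methanotrophic archaea) or `other`.
#'
#' @param path Delimited file with columns `taxon_id`, `group`, `role`.
#' @inheritParams read_profile_table
#' @return A validated tibble.
#' @export
read_group_map <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  validate_group_map(reader(path, show_col_types = FALSE, progress = FALSE))
}

#' @rdname read_group_map
#' @param x A data frame mapping taxa to groups and roles.
#' @export
validate_group_map <- function(x) {
  required <- c("taxon_id", "group", "role")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    seep_abort(paste0("group map is missing column(s): ",
                      paste(missing, collapse = ", ")), "seep_format_error")
  }
  x <- tibble::as_tibble(x)
  dup <- unique(x$taxon_id[duplicated(x$taxon_id)])
  if (length(dup) > 0) {
    seep_abort(paste0("duplicate taxon_id(s): ", paste(dup, collapse = ", ")),
               "seep_validation_error")
  }
  bad <- setdiff(unique(x$role), c("SRB", "ANME", "other"))
  if (length(bad) > 0) {
    seep_abort(paste0("role must be one of SRB, ANME, other; got: ",
                      paste(bad, collapse = ", ")), "seep_validation_error")
  }
  x
}
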