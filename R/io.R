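#' Read a FISH distance table
#'
#' Accepts the two CSV/TSV dialects the fitting and deconvolution functions
#' consume: per-cell distances (columns `pair_id`, `distance_um`) or a
#' pre-tabulated empirical CDF (columns `pair_id`, `r_um`, `cdf`). Malformed
#' rows are reported with their line numbers.
#'
#' @param path File path (delimiter inferred from the extension: `.tsv` is
#'   tab, otherwise comma).
#' @return A validated tibble in one of the two dialects.
#' @export
read_fish <- function(path) {
  df <- read_table_auto(path)
  nm <- names(df)
  if (all(c("pair_id", "distance_um") %in% nm)) {
    bad <- which(!is.finite(df$distance_um) | df$distance_um < 0)
    if (length(bad)) {
      abort(sprintf("negative or missing distances at data line(s): %s",
                    paste(head(bad, 5), collapse = ", ")))
    }
    return(df[c("pair_id", "distance_um")])
  }
  if (all(c("pair_id", "r_um", "cdf") %in% nm)) {
    bad <- which(!is.finite(df$cdf) | df$cdf < 0 | df$cdf > 1 |
                   !is.finite(df$r_um) | df$r_um < 0)
    if (length(bad)) {
      abort(sprintf("invalid CDF rows at data line(s): %s",
                    paste(head(bad, 5), collapse = ", ")))
    }
    return(df[c("pair_id", "r_um", "cdf")])
  }
  abort("FISH file must have columns pair_id + distance_um, or pair_id + r_um + cdf")
}

#' Read a Hi-C contact-count table
#'
#' @param path CSV/TSV with columns `pair_id`, `contact_count`.
#' @return A validated tibble.
#' @export
read_hic_counts <- function(path) {
  df <- read_table_auto(path)
  if (!all(c("pair_id", "contact_count") %in% names(df))) {
    abort("Hi-C file must have columns pair_id, contact_count")
  }
  bad <- which(!is.finite(df$contact_count) | df$contact_count < 0)
  if (length(bad)) {
    abort(sprintf("negative or missing counts at data line(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  df[c("pair_id", "contact_count")]
}

#' Read loop anchors from a BEDPE file
#'
#' Reads the first six BEDPE columns (`chrom1 start1 end1 chrom2 start2
#' end2`, 0-based half-open) and maps each anchor to a monomer index by
#' `floor(start / bin_size) + 1` (so genomic start 0 falls in bin 0, the
#' first monomer). Interchromosomal rows are rejected.
#'
#' @param path BEDPE path (tab- or comma-separated; header optional,
#'   detected by a non-numeric second field).
#' @param bin_size Genomic bin per monomer, in bp.
#' @return A tibble with `chrom`, `start1`, `start2`, `monomer1`, `monomer2`.
#' @export
read_bedpe <- function(path, bin_size = 1200) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("empty BEDPE file")
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  first <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  skip_header <- length(first) >= 2 && is.na(suppressWarnings(as.numeric(first[2])))
  if (skip_header) lines <- lines[-1]
  rows <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(vapply(rows, length, integer(1)) < 6)
  if (length(bad)) {
    abort(sprintf("malformed BEDPE row(s) with < 6 fields at line(s): %s",
                  paste(head(bad + skip_header, 5), collapse = ", ")))
  }
  df <- tibble::tibble(
    chrom1 = vapply(rows, `[[`, character(1), 1),
    start1 = as.numeric(vapply(rows, `[[`, character(1), 2)),
    chrom2 = vapply(rows, `[[`, character(1), 4),
    start2 = as.numeric(vapply(rows, `[[`, character(1), 5))
  )
  if (any(is.na(df$start1)) || any(is.na(df$start2))) {
    abort("non-numeric start coordinate in BEDPE")
  }
  if (any(df$chrom1 != df$chrom2)) {
    abort("interchromosomal BEDPE rows are not supported")
  }
  df |>
    dplyr::transmute(chrom = .data$chrom1, start1 = .data$start1,
                     start2 = .data$start2,
                     monomer1 = as.integer(floor(.data$start1 / bin_size)) + 1L,
                     monomer2 = as.integer(floor(.data$start2 / bin_size)) + 1L)
}

#' @rdname read_bedpe
#' @param bedpe A tibble as returned by `read_bedpe()`.
#' @export
bedpe_to_loops <- function(bedpe) {
  loop_set(cbind(bedpe$monomer1, bedpe$monomer2))
}

read_table_auto <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.size(path) == 0) abort(sprintf("empty input file: %s", path))
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (!nrow(df)) abort(sprintf("no data rows in %s", path))
  df
}

#' Write a results table
#'
#' @param x A data frame.
#' @param path Output CSV path (directories are created).
#' @return `x`, invisibly.
#' @export
write_results <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(x, path)
  invisible(x)
}

#' Reconcile FISH distance data with Hi-C counts
#'
#' The end-to-end workflow on tabular inputs: fit a two-subpopulation
#' mixture to each pair's FISH distances, predict each pair's contact
#' probability at threshold `r_c`, convert both predictions and Hi-C counts
#' to relative contact frequencies (`P_i / mean(P)`), and report their
#' Pearson correlation. Pairs present in only one table are reported and
#' skipped.
#'
#' @param fish Tidy FISH table (`pair_id`, `distance_um`).
#' @param hic Hi-C counts table (`pair_id`, `contact_count`).
#' @param r_c Contact threshold in the distance units of `fish` (the
#'   default 0.01 um = 10 nm; 0.02 um is the common alternative).
#' @param family,g,delta Component family as in [mixture_model()].
#' @return An object of class `fishhic_reconciliation`: list with `fits`
#'   (per-pair mixture summaries), `comparison` (per-pair predicted and
#'   measured relative frequencies), `pearson`, `skipped_pairs` and the
#'   run parameters.
#' @examples
#' set.seed(2)
#' fish <- dplyr::bind_rows(
#'   sample_distances(mixture_model(0.3, 0.3, 1.2), 300, pair_id = "a"),
#'   sample_distances(mixture_model(0.8, 0.3, 1.2), 300, pair_id = "b"))
#' hic <- sample_hic_counts(c(1e-4, 3e-4), depth = 1e6,
#'                          pair_id = c("a", "b"))
#' rec <- pipeline_reconcile(fish, hic, r_c = 0.02)
#' @export
pipeline_reconcile <- function(fish, hic, r_c = 0.01,
                               family = c("chi", "rdc"), g = 1,
                               delta = 5 / 4) {
  family <- match.arg(family)
  if (!all(c("pair_id", "contact_count") %in% names(hic))) {
    abort("`hic` must have columns pair_id, contact_count")
  }
  common <- intersect(unique(fish$pair_id), unique(hic$pair_id))
  skipped <- setdiff(union(unique(fish$pair_id), unique(hic$pair_id)), common)
  if (length(skipped)) {
    warn(sprintf("skipping %d pair(s) missing from one table: %s",
                 length(skipped), paste(head(skipped, 10), collapse = ", ")))
  }
  if (length(common) < 2) abort("need >= 2 pairs present in both tables")
  fits <- fit_mixture_pairs(dplyr::filter(fish, .data$pair_id %in% common),
                            family = family, g = g, delta = delta, r_c = r_c)
  comparison <- fits |>
    dplyr::select("pair_id", "predicted_contact_prob") |>
    dplyr::inner_join(
      dplyr::distinct(hic, .data$pair_id, .keep_all = TRUE)[
        c("pair_id", "contact_count")],
      by = "pair_id") |>
    dplyr::mutate(
      predicted_relative = relative_contact_frequencies(.data$predicted_contact_prob),
      hic_relative = relative_contact_frequencies(.data$contact_count))
  structure(list(
    fits = fits, comparison = comparison,
    pearson = cor(comparison$predicted_relative, comparison$hic_relative),
    skipped_pairs = skipped,
    params = list(r_c = r_c, family = family, g = g, delta = delta)),
    class = "fishhic_reconciliation")
}

#' @export
print.fishhic_reconciliation <- function(x, ...) {
  cat(sprintf(
    "<fishhic_reconciliation> %d pairs, r_c = %g, family = %s\n  Pearson(predicted vs Hi-C relative frequency) = %.3f\n",
    nrow(x$comparison), x$params$r_c, x$params$family, x$pearson))
  if (length(x$skipped_pairs)) {
    cat("  skipped:", paste(x$skipped_pairs, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname pipeline_reconcile
#' @param x,object A `fishhic_reconciliation`.
#' @param ... Unused.
#' @export
glance.fishhic_reconciliation <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$comparison), pearson = x$pearson,
                 n_skipped = length(x$skipped_pairs),
                 r_c = x$params$r_c, family = x$params$family)
}

#' @rdname pipeline_reconcile
#' @export
autoplot.fishhic_reconciliation <- function(object, ...) {
  df <- object$comparison |>
    tidyr::pivot_longer(c("predicted_relative", "hic_relative"),
                        names_to = "source", values_to = "relative_frequency")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair_id,
                                   y = .data$relative_frequency,
                                   fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "relative contact frequency", fill = NULL) +
    ggplot2::theme_minimal()
}
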