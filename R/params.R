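## Library-design parameter algebra: the coverage identity C = C_F x C_R,
## fragment-length summaries, and validated design points.

#' Total sequence coverage implied by physical and per-fragment coverage
#'
#' In Linked-Read sequencing the total short-read coverage of the genome
#' factorises as `C = C_F * C_R`: `C_F` is the physical coverage by long
#' DNA fragments (summed fragment length over haploid genome length) and
#' `C_R` is the mean short-read coverage attained within a single fragment.
#'
#' @param c_f Physical (fragment) coverage, fold. Must be positive.
#' @param c_r Per-fragment read coverage, fold. Must be positive.
#' @return Total coverage `C` (fold).
#' @examples
#' total_coverage(300, 0.2)  # 60
#' @export
total_coverage <- function(c_f, c_r) {
  if (!is.numeric(c_f) || !is.numeric(c_r) || any(c_f <= 0) || any(c_r <= 0)) {
    stop_invalid("c_f and c_r must be positive numbers")
  }
  c_f * c_r
}

#' Length-weighted mean fragment length
#'
#' The length-weighted mean WmuFL weights each fragment by its own length:
#' `sum(L^2) / sum(L)`. It is the expected length of the fragment containing
#' a uniformly chosen base, and always dominates the unweighted mean. For
#' exponentially distributed lengths with mean mu it equals `2 * mu`.
#'
#' @param lengths Numeric vector of positive fragment lengths (bp).
#' @return Weighted mean length (bp).
#' @export
weighted_mean_fragment_length <- function(lengths) {
  if (length(lengths) == 0L) stop_invalid("empty length list")
  if (!is.numeric(lengths) || any(lengths <= 0) || anyNA(lengths)) {
    stop_invalid("lengths must be positive and non-missing")
  }
  sum(lengths^2) / sum(lengths)
}

#' Summarise a fragment-length sample
#'
#' Computes the unweighted mean (muFL), length-weighted mean (WmuFL), count
#' and total bases of a fragment-length sample, together with binned
#' PDF/CDF/reverse-CDF tables of the unweighted lengths and the
#' reverse-CDF of length-weighted mass (the fraction of total bases lying
#' in fragments of at least a given length).
#'
#' @param lengths Numeric vector of positive fragment lengths (bp).
#' @param n_bins Number of histogram bins for the distribution tables.
#' @return An object of class `fragment_length_summary`: a list with
#'   `mu_fl`, `w_mu_fl`, `n_fragments`, `total_bases` and a `tables`
#'   element holding `pdf`, `cdf`, `rev_cdf` and `weighted_rev_cdf`
#'   data.tables keyed by bin midpoint / threshold length.
#' @export
summarize_lengths <- function(lengths, n_bins = 100L) {
  if (length(lengths) == 0L) stop_invalid("empty length list")
  if (any(lengths <= 0) || anyNA(lengths)) {
    stop_invalid("lengths must be positive and non-missing")
  }
  lengths <- as.numeric(lengths)
  total <- sum(lengths)
  brks <- seq(0, max(lengths), length.out = n_bins + 1L)
  if (length(unique(brks)) < 2L) brks <- c(0, max(lengths))
  bin <- cut(lengths, brks, include.lowest = TRUE, labels = FALSE)
  counts <- tabulate(bin, nbins = length(brks) - 1L)
  mass <- vapply(seq_along(counts), function(i) sum(lengths[bin == i]), 0)
  mids <- (head(brks, -1L) + tail(brks, -1L)) / 2
  pdf <- data.table(length = mids, density = counts / sum(counts))
  cdf <- data.table(length = tail(brks, -1L), cum_frac = cumsum(counts) / sum(counts))
  rev_cdf <- data.table(length = head(brks, -1L),
                        frac_ge = rev(cumsum(rev(counts))) / sum(counts))
  wrev <- data.table(length = head(brks, -1L),
                     mass_frac_ge = rev(cumsum(rev(mass))) / total)
  structure(
    list(mu_fl = mean(lengths),
         w_mu_fl = weighted_mean_fragment_length(lengths),
         n_fragments = length(lengths),
         total_bases = total,
         tables = list(pdf = pdf, cdf = cdf, rev_cdf = rev_cdf,
                       weighted_rev_cdf = wrev)),
    class = "fragment_length_summary"
  )
}

#' @export
print.fragment_length_summary <- function(x, ...) {
  cat(sprintf("Fragment lengths: n = %d, total = %.0f bp\n",
              x$n_fragments, x$total_bases))
  cat(sprintf("  muFL  = %.1f bp (unweighted mean)\n", x$mu_fl))
  cat(sprintf("  WmuFL = %.1f bp (length-weighted mean)\n", x$w_mu_fl))
  invisible(x)
}

#' Construct and validate a Linked-Read library design point
#'
#' Exactly two of `c`, `c_f` and `c_r` must be supplied; the third is
#' derived from the identity `C = C_F * C_R`. If all three are supplied
#' they must satisfy the identity to within 1e-9 relative.
#'
#' @param c Total sequence coverage (fold).
#' @param c_f Physical fragment coverage of the haploid genome (fold).
#' @param c_r Mean read coverage per fragment (fold).
#' @param n_fp Mean fragments per partition.
#' @param mu_fl Unweighted mean fragment length (bp).
#' @param read_len Bases per read end (bp).
#' @param insert_mean,insert_sd Short-fragment insert-size model (bp).
#' @param error_rate Per-base substitution probability, in `[0, 1)`.
#' @param barcode_len Barcode length (bp); 16 for the Chromium system.
#' @param n_spacer Number of N spacer bases after the barcode; 7.
#' @param seed Master RNG seed.
#' @return An object of class `library_params` (a named list).
#' @examples
#' p <- library_params(c_f = 300, c_r = 0.2)
#' p$c  # 60
#' @export
library_params <- function(c = NULL, c_f = NULL, c_r = NULL, n_fp = 10,
                           mu_fl = 37000, read_len = 150L,
                           insert_mean = 500, insert_sd = 50,
                           error_rate = 0, barcode_len = 16L, n_spacer = 7L,
                           seed = 1L) {
  given <- !vapply(list(c, c_f, c_r), is.null, logical(1))
  if (sum(given) < 2L) {
    stop_invalid("at least two of c, c_f, c_r must be specified")
  }
  if (sum(given) == 3L) {
    if (abs(c - c_f * c_r) > 1e-9 * abs(c)) {
      stop_invalid("inconsistent coverages: c = %g but c_f * c_r = %g",
                   c, c_f * c_r)
    }
  } else if (is.null(c)) {
    c <- total_coverage(c_f, c_r)
  } else if (is.null(c_f)) {
    c_f <- c / c_r
  } else {
    c_r <- c / c_f
  }
  for (nm in c("c", "c_f", "c_r", "n_fp", "mu_fl", "read_len",
               "insert_mean", "insert_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stop_invalid("'%s' must be a single positive number", nm)
    }
  }
  if (error_rate < 0 || error_rate >= 1) {
    stop_invalid("error_rate must lie in [0, 1)")
  }
  structure(
    list(c = c, c_f = c_f, c_r = c_r, n_fp = n_fp, mu_fl = mu_fl,
         read_len = as.integer(read_len), insert_mean = insert_mean,
         insert_sd = insert_sd, error_rate = error_rate,
         barcode_len = as.integer(barcode_len),
         n_spacer = as.integer(n_spacer), seed = as.integer(seed)),
    class = "library_params"
  )
}

#' @export
print.library_params <- function(x, ...) {
  cat("Linked-Read library design point\n")
  cat(sprintf("  C = %.3g x  (C_F = %.4g x, C_R = %.4g x)\n", x$c, x$c_f, x$c_r))
  cat(sprintf("  N_F/P = %.3g, muFL = %.4g bp\n", x$n_fp, x$mu_fl))
  cat(sprintf("  reads: 2 x %d bp, insert %g +/- %g bp, error %.3g\n",
              x$read_len, x$insert_mean, x$insert_sd, x$error_rate))
  invisible(x)
}

#' Genomic bases contributed per read pair
#'
#' The first `barcode_len + n_spacer` bases of every forward read carry the
#' partition barcode and spacer, not genomic sequence, so a pair contributes
#' `2 * read_len - barcode_len - n_spacer` genomic bases (277 under the
#' defaults). Coverage accounting throughout the package counts genomic
#' bases only.
#'
#' @param params A `library_params` object, or NULL for the defaults.
#' @return Integer number of genomic bases per pair.
#' @export
genomic_bases_per_pair <- function(params = NULL) {
  if (is.null(params)) return(277L)
  as.integer(2L * params$read_len - params$barcode_len - params$n_spacer)
}

#' Read a flat key-value parameter configuration file
#'
#' One `key = value` pair per line; blank lines and `#` comments ignored.
#' Values that parse as numbers are returned numeric.
#'
#' @param path Path to the config file.
#' @return A named list.
#' @export
read_params_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop_invalid("malformed config line (expected 'key = value'): '%s'", ln)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write a flat key-value parameter configuration file
#'
#' @param params A named list or `library_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params_config <- function(params, path) {
  stopifnot(!is.null(names(params)))
  lines <- vapply(names(params), function(k) {
    sprintf("%s = %s", k, format(params[[k]], scientific = FALSE))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
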