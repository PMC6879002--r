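## Run configuration handling and the bundled end-to-end fixture pipeline.

#' Validate and complete a run configuration
#'
#' Applies the coverage identity (deriving the third of `c`/`c_f`/`c_r`),
#' rejects contradictory over-specification, fills documented defaults and
#' warns when the expected partition count exceeds the 4.8 million barcode
#' limit (computable only when a reference length is known).
#'
#' @param raw Named list of raw settings (e.g. from
#'   [read_params_config()] merged with command-line flags; flags should
#'   already override file values).
#' @return list of class `run_config`: `params` (a `library_params`),
#'   `seed`, `out_prefix`, `ref_len` (may be NA), plus any extra settings
#'   passed through.
#' @export
validate_config <- function(raw) {
  known <- c("c", "c_f", "c_r", "n_fp", "mu_fl", "read_len", "insert_mean",
             "insert_sd", "error_rate", "seed")
  args <- raw[intersect(names(raw), known)]
  if (is.null(args$c) && is.null(args$c_f) && is.null(args$c_r)) {
    args$c_f <- 200
    args$c_r <- 0.2
  }
  params <- do.call(library_params, args)
  ref_len <- raw$ref_len %||% NA_real_
  if (!is.na(ref_len)) {
    n_partitions <- params$c_f * ref_len / params$mu_fl / params$n_fp
    if (n_partitions > 4.8e6) {
      warning(sprintf(
        "expected %.2g partitions exceed the 4.8 million barcode limit",
        n_partitions))
    }
  }
  extra <- raw[setdiff(names(raw), c(known, "ref_len"))]
  structure(c(list(params = params, seed = params$seed,
                   out_prefix = raw$out_prefix %||% "lrkit_run",
                   ref_len = ref_len),
              extra),
            class = "run_config")
}

#' Run the bundled end-to-end fixture pipeline
#'
#' Generates a synthetic reference (tiny: 200 kb over 2 contigs; small:
#' 2 Mb over 2 contigs), builds a diploid template, simulates a library at
#' the default design point (`C_F` = 200, `C_R` = 0.2, muFL = 37 kb,
#' `N_F/P` = 10), reconstructs molecules from the truth table, and writes
#' a recovery report comparing realized to requested parameters together
#' with a run manifest (parameters, seed, output checksums).
#'
#' @param scale `"tiny"` or `"small"`.
#' @param seed Master seed.
#' @param out_dir Output directory (created if needed).
#' @param params Optional `library_params` overriding the default design
#'   point (its seed is replaced by `seed`).
#' @param write_fastq Also emit FASTQ output (tiny scale only by default
#'   of the caller; sequences are generated whenever TRUE).
#' @return list of class `fixture_result`: `status` (0 on success),
#'   `manifest_path`, `manifest`, `recovery` (data.table of requested /
#'   realized / relative error per parameter), `profile`.
#' @export
run_fixture_pipeline <- function(scale = c("tiny", "small"), seed = 1L,
                                 out_dir = tempfile("lrkit_fixture_"),
                                 params = NULL, write_fastq = FALSE) {
  scale <- match.arg(scale)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  contig_len <- if (scale == "tiny") 100000L else 1000000L
  if (is.null(params)) {
    params <- library_params(c_f = 200, c_r = 0.2, mu_fl = 37000,
                             n_fp = 10, seed = seed)
  } else {
    params$seed <- as.integer(seed)
  }
  spec <- synthetic_reference_spec(n_contigs = 2L, contig_len = contig_len,
                                   gc_content = 0.41, seed = seed)
  ref <- generate_reference(spec)
  template <- build_template(ref, seed = seed)
  lib <- simulate_library(template, params, with_sequences = write_fastq)
  paths <- character(0)
  if (write_fastq) {
    paths <- write_linked_fastq(lib$reads, file.path(out_dir, "library"))
  } else {
    truth_path <- file.path(out_dir, "library_truth.tsv")
    truth_cols <- c("read_id", "barcode", "partition_id", "fragment_id",
                    "haplotype", "contig", "frag_start", "frag_end",
                    "r1_start", "r2_start", "insert_len")
    fwrite(as.data.table(lib$reads)[, ..truth_cols], truth_path, sep = "\t")
    paths <- c(truth = truth_path)
  }
  placements <- placements_from_truth(paths[["truth"]])
  inferred <- infer_fragments(placements, use_provenance = TRUE)
  profile <- profile_library(inferred, ref_len = template$source_len)
  recovery <- data.table(
    parameter = c("c_f", "c_r", "mu_fl", "n_fp"),
    requested = c(params$c_f, params$c_r, params$mu_fl, params$n_fp),
    realized = c(profile$c_f, profile$c_r, profile$length_summary$mu_fl,
                 profile$n_fp))
  recovery[, rel_error := abs(realized - requested) / requested]
  fwrite(recovery, file.path(out_dir, "recovery_report.tsv"), sep = "\t")
  manifest <- list(
    tool = "lrkit",
    version = as.character(utils::packageVersion("lrkit")),
    scale = scale,
    seed = as.integer(seed),
    parameters = unclass(params),
    n_fragments = nrow(lib$fragments),
    n_partitions = nrow(lib$partitions$partitions),
    n_read_pairs = nrow(lib$reads),
    outputs = {
      sums <- tools::md5sum(unname(
        c(paths, file.path(out_dir, "recovery_report.tsv"))))
      names(sums) <- basename(names(sums))
      as.list(sums)
    }
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  structure(list(status = 0L, manifest_path = manifest_path,
                 manifest = manifest, recovery = recovery,
                 profile = profile, out_dir = out_dir),
            class = "fixture_result")
}

#' @export
print.fixture_result <- function(x, ...) {
  cat(sprintf("Fixture pipeline run (%s): status %d\n",
              x$manifest$scale, x$status))
  print(x$recovery)
  invisible(x)
}
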