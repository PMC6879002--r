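## Molecule reconstruction from barcode-grouped read placements, library
## profiling, and barcode-aware subsampling.
##
## The inference follows the standard proximity chaining: read pairs with
## the same barcode aligned close to each other are taken to come from one
## long molecule; a molecule is terminated when the gap to the next
## same-barcode pair exceeds 50 kb; reconstructed molecules need >= 2 read
## pairs and >= 2 kb; barcodes retaining < 3 molecules are removed.

#' Gap between two consecutive same-barcode read placements
#'
#' Measured end-to-start between the pair spans (`p2` leftmost minus `p1`
#' rightmost), floored at zero for abutting or overlapping placements.
#' Placements on different contigs are infinitely far apart, forcing a
#' molecule split.
#'
#' @param p1,p2 Placements (lists/rows with `contig`, `leftmost`,
#'   `rightmost`), `p1` not to the right of `p2`.
#' @return Gap in bp (possibly `Inf`).
#' @export
measure_gap_distance <- function(p1, p2) {
  if (!identical(as.character(p1$contig), as.character(p2$contig))) return(Inf)
  if (p2$leftmost < p1$leftmost) stop_invalid("p1 must not lie right of p2")
  max(p2$leftmost - p1$rightmost, 0)
}

#' Convert a truth table (or file) to read placements
#'
#' The pair's outer span on the reference is `[r1_start,
#' r1_start + insert_len)`.
#'
#' @param truth A truth data.table from [generate_reads()] /
#'   [write_linked_fastq()], or a path to the truth TSV.
#' @return data.table of placements: `read_id`, `barcode`, `contig`,
#'   `leftmost`, `rightmost` (plus truth provenance columns when present).
#' @export
placements_from_truth <- function(truth) {
  if (is_string(truth)) truth <- fread(truth, sep = "\t")
  truth <- as.data.table(truth)
  out <- truth[, .(read_id, barcode, contig, leftmost = r1_start,
                   rightmost = r1_start + insert_len)]
  for (col in c("fragment_id", "partition_id", "haplotype")) {
    if (col %in% names(truth)) out[[col]] <- truth[[col]]
  }
  out
}

#' Read pair placements from a coordinate-sorted SAM/BAM file
#'
#' Barcodes are taken from the `BX` tag. Secondary, supplementary,
#' unmapped, duplicate-marked records and records without a `BX` tag are
#' skipped; skip counts are attached as the `skipped` attribute. Each
#' properly oriented pair contributes one placement spanning from the
#' leftmost mate start to the rightmost mate end.
#'
#' @param path SAM or BAM path.
#' @return data.table of placements (`read_id`, `barcode`, `contig`,
#'   `leftmost`, `rightmost`), 0-based half-open.
#' @export
read_placements_sam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else {
    bam <- path
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag, tag = "BX",
    what = c("qname", "rname", "pos", "cigar"))
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n_in <- length(res$qname)
  bx <- res$tag$BX
  if (is.null(bx)) bx <- rep(NA_character_, n_in)
  keep <- !is.na(bx) & !is.na(res$pos)
  skipped <- c(no_bx_or_unusable = sum(!keep))
  ref_width <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar[keep])
  dt <- data.table(qname = res$qname[keep],
                   barcode = bx[keep],
                   contig = as.character(res$rname)[keep],
                   s = res$pos[keep] - 1L,
                   e = res$pos[keep] - 1L + ref_width)
  placements <- dt[, .(barcode = barcode[1L],
                       leftmost = min(s), rightmost = max(e)),
                   by = .(read_id = qname, contig)]
  setattr(placements, "skipped", skipped)
  placements[]
}

#' Reconstruct long DNA molecules from barcoded read placements
#'
#' Within each (barcode, contig) group, placements sorted by leftmost
#' coordinate are chained into molecules; a new molecule starts when the
#' end-to-start gap between consecutive placements exceeds
#' `gap_kb * 1000`. The molecule span runs from the first leftmost to the
#' last rightmost coordinate. Molecules with fewer than `min_pairs` read
#' pairs or shorter than `min_len_kb * 1000` are discarded, and barcodes
#' retaining fewer than `min_frags_per_partition` molecules are then
#' removed entirely. The result is invariant to input order.
#'
#' @param placements data.table with `read_id`, `barcode`, `contig`,
#'   `leftmost`, `rightmost`.
#' @param gap_kb Termination gap (kb).
#' @param min_pairs Minimum read pairs per molecule.
#' @param min_len_kb Minimum molecule length (kb).
#' @param min_frags_per_partition Minimum molecules per retained barcode.
#' @param use_provenance When TRUE and the placements carry a
#'   `fragment_id` column (truth-sidecar input), chaining is additionally
#'   keyed by the true source fragment, so reads from different true
#'   molecules are never chained together; all filters apply unchanged.
#'   This is the ground-truth recovery path — at toy genome scales the
#'   barcode-proximity heuristic merges co-barcoded molecules that happen
#'   to land within the termination gap of each other, an artifact that
#'   vanishes at real genome sizes. Alignment input has no provenance and
#'   always uses plain barcode chaining.
#' @return data.table of class `inferred_fragments`: `fragment_id`,
#'   `barcode`, `contig`, `start`, `end`, `len`, `n_read_pairs`,
#'   `read_ids` (list column).
#' @export
infer_fragments <- function(placements, gap_kb = 50, min_pairs = 2L,
                            min_len_kb = 2, min_frags_per_partition = 3L,
                            use_provenance = FALSE) {
  pl <- as.data.table(placements)
  if (use_provenance) {
    if (!"fragment_id" %in% names(pl)) {
      stop_invalid("use_provenance requires a fragment_id column")
    }
    setnames(pl, "fragment_id", "src_fragment")
  }
  empty <- data.table(fragment_id = integer(), barcode = character(),
                      contig = character(), start = integer(),
                      end = integer(), len = integer(),
                      n_read_pairs = integer(), read_ids = list())
  if (nrow(pl) == 0L) return(empty)
  key_cols <- c("barcode", "contig", if (use_provenance) "src_fragment")
  setorderv(pl, c(key_cols, "leftmost", "rightmost"))
  gap_bp <- gap_kb * 1000
  pl[, frag_grp := {
    gap <- leftmost - shift(rightmost)
    cumsum(c(TRUE, gap[-1L] > gap_bp))
  }, by = key_cols]
  frags <- pl[, .(start = min(leftmost), end = max(rightmost),
                  n_read_pairs = .N, read_ids = list(read_id)),
              by = c(key_cols, "frag_grp")]
  frags[, len := end - start]
  frags <- frags[n_read_pairs >= min_pairs & len >= min_len_kb * 1000]
  frags <- frags[, if (.N >= min_frags_per_partition) .SD, by = barcode]
  if (nrow(frags) == 0L) return(empty)
  frags[, frag_grp := NULL]
  if (use_provenance) frags[, src_fragment := NULL]
  frags[, fragment_id := seq_len(.N)]
  setcolorder(frags, c("fragment_id", "barcode", "contig", "start", "end",
                       "len", "n_read_pairs", "read_ids"))
  setattr(frags, "class", c("inferred_fragments", class(frags)))
  frags[]
}

#' Profile a Linked-Read library from reconstructed molecules
#'
#' Produces the standard library-profile statistics: number of partitions,
#' molecules-per-partition histogram, per-molecule sequencing-depth
#' histogram, the fragment-length summary (unweighted/weighted means and
#' distribution tables) and the estimated design parameters: `C_F` (summed
#' molecule length over reference length), `C_R` (genomic read bases
#' within molecules over summed molecule length) and `N_F/P` (mean
#' molecules per retained partition).
#'
#' @param fragments An `inferred_fragments` table.
#' @param ref_len Haploid reference length (bp).
#' @param bases_per_pair Genomic bases per read pair (see
#'   [genomic_bases_per_pair()]).
#' @return An object of class `library_profile`, or an empty-profile
#'   marker (`n_fragments = 0`) for empty input.
#' @export
profile_library <- function(fragments, ref_len,
                            bases_per_pair = genomic_bases_per_pair()) {
  fr <- as.data.table(fragments)
  if (nrow(fr) == 0L) {
    return(structure(list(n_fragments = 0L), class = "library_profile"))
  }
  fpp <- fr[, .N, by = barcode]$N
  depth <- fr$n_read_pairs * bases_per_pair / fr$len
  structure(
    list(n_fragments = nrow(fr),
         n_partitions = length(fpp),
         fragments_per_partition = tabulate(fpp, nbins = max(fpp)),
         depth_hist = graphics::hist(depth, breaks = 30L, plot = FALSE),
         length_summary = summarize_lengths(fr$len),
         c_f = sum(as.numeric(fr$len)) / ref_len,
         c_r = sum(as.numeric(fr$n_read_pairs)) * bases_per_pair /
           sum(as.numeric(fr$len)),
         n_fp = mean(fpp),
         ref_len = ref_len),
    class = "library_profile"
  )
}

#' @export
print.library_profile <- function(x, ...) {
  if (x$n_fragments == 0L) {
    cat("Library profile: empty (no molecules survived filtering)\n")
    return(invisible(x))
  }
  cat(sprintf("Library profile: %d molecules in %d partitions\n",
              x$n_fragments, x$n_partitions))
  cat(sprintf("  estimated C_F = %.1f x, C_R = %.3f x, N_F/P = %.2f\n",
              x$c_f, x$c_r, x$n_fp))
  cat(sprintf("  muFL = %.0f bp, WmuFL = %.0f bp\n",
              x$length_summary$mu_fl, x$length_summary$w_mu_fl))
  invisible(x)
}

#' Write library-profile tables as TSV files
#'
#' One file per panel: molecules per partition (A), per-molecule depth
#' (B), fragment-length PDF (C), CDF (D), reverse CDF (E) and reverse CDF
#' of length-weighted mass (F).
#'
#' @param profile A `library_profile`.
#' @param out_prefix Output path prefix.
#' @return Character vector of paths written, invisibly.
#' @export
write_profile_tsvs <- function(profile, out_prefix) {
  if (profile$n_fragments == 0L) stop_invalid("empty profile")
  paths <- paste0(out_prefix, "_", c(
    "fragments_per_partition", "depth_per_fragment", "length_pdf",
    "length_cdf", "length_revcdf", "length_weighted_revcdf"), ".tsv")
  fwrite(data.table(n_fragments = seq_along(profile$fragments_per_partition),
                    n_partitions = profile$fragments_per_partition),
         paths[1L], sep = "\t")
  h <- profile$depth_hist
  fwrite(data.table(depth_mid = h$mids, n_fragments = h$counts),
         paths[2L], sep = "\t")
  tb <- profile$length_summary$tables
  fwrite(tb$pdf, paths[3L], sep = "\t")
  fwrite(tb$cdf, paths[4L], sep = "\t")
  fwrite(tb$rev_cdf, paths[5L], sep = "\t")
  fwrite(tb$weighted_rev_cdf, paths[6L], sep = "\t")
  invisible(paths)
}

#' Subsample read pairs within each molecule to a target coverage
#'
#' Per molecule, `round(target_cr * len / bases_per_pair)` pairs are kept
#' by uniform sampling without replacement, capped at the available count.
#' Deterministic under `seed`.
#'
#' @param fragments An `inferred_fragments` table (with `read_ids`).
#' @param target_cr Target per-molecule read coverage (fold).
#' @param bases_per_pair Genomic bases per pair.
#' @param seed RNG seed.
#' @return Character vector of retained read ids.
#' @export
subsample_reads <- function(fragments, target_cr,
                            bases_per_pair = genomic_bases_per_pair(),
                            seed = 1L) {
  if (target_cr <= 0) stop_invalid("target_cr must be positive")
  fr <- as.data.table(fragments)
  if (nrow(fr) == 0L) return(character(0))
  with_stage_seed(seed, "subsample_reads", {
    keep <- lapply(seq_len(nrow(fr)), function(i) {
      ids <- fr$read_ids[[i]]
      k <- min(length(ids), round(target_cr * fr$len[i] / bases_per_pair))
      if (k >= length(ids)) ids else sample(ids, k)
    })
    unlist(keep, use.names = FALSE)
  })
}

#' Subsample molecules to a target physical coverage
#'
#' Molecules are dropped uniformly at random until the summed length per
#' reference length first falls to at most `target_cf`. Identity when the
#' current coverage is already at or below the target.
#'
#' @param fragments An `inferred_fragments` (or `fragment_set`) table with
#'   a `len` column.
#' @param target_cf Target physical coverage (fold).
#' @param ref_len Haploid reference length (bp).
#' @param seed RNG seed.
#' @return The retained subset of `fragments`.
#' @export
subsample_fragments <- function(fragments, target_cf, ref_len, seed = 1L) {
  if (target_cf <= 0) stop_invalid("target_cf must be positive")
  fr <- as.data.table(fragments)
  total <- sum(as.numeric(fr$len))
  target_bases <- target_cf * ref_len
  if (total <= target_bases) return(fragments)
  with_stage_seed(seed, "subsample_fragments", {
    drop_order <- sample.int(nrow(fr))
    removed <- cumsum(as.numeric(fr$len[drop_order]))
    n_drop <- which(total - removed <= target_bases)[1L]
    fragments[-drop_order[seq_len(n_drop)], ]
  })
}

#' Filter a paired FASTQ library down to a retained read-id set
#'
#' Re-filters the original R1/R2 files written by [write_linked_fastq()],
#' preserving order.
#'
#' @param in_prefix Prefix of the original `_R1/_R2.fastq.gz` pair.
#' @param keep_ids Character vector of read ids to retain.
#' @param out_prefix Prefix for the filtered pair.
#' @return Named character vector of output paths, invisibly.
#' @export
filter_linked_fastq <- function(in_prefix, keep_ids, out_prefix) {
  keep_set <- unique(keep_ids)
  out <- c(r1 = paste0(out_prefix, "_R1.fastq.gz"),
           r2 = paste0(out_prefix, "_R2.fastq.gz"))
  for (side in c("r1", "r2")) {
    lines <- readLines(gzfile(paste0(in_prefix, "_",
                                     toupper(side), ".fastq.gz")))
    ids <- sub("^@", "", lines[seq(1L, length(lines), by = 4L)])
    sel <- which(ids %in% keep_set)
    rows <- as.vector(vapply(sel, function(i) (i - 1L) * 4L + 1:4,
                             integer(4)))
    con <- gzfile(out[[side]], "wb")
    writeLines(lines[rows], con)
    close(con)
  }
  invisible(out)
}
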