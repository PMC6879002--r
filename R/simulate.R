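## The Linked-Read library simulation engine: exponential shearing of each
## haplotype into long fragments at a target physical coverage, Poisson
## allocation of fragments to barcoded partitions, and generation of
## barcode-prefixed paired-end short reads at a target per-fragment read
## coverage.

#' Shear a diploid template into long DNA fragments
#'
#' Whole-genome copies of each haplotype are sheared by drawing successive
#' exponential(`mu_fl`) lengths from position 0 to the contig end (the last
#' piece truncated at the end); pieces shorter than `min_len` are
#' discarded. Copies are generated until the retained bases per haplotype
#' reach `(c_f / 2) * source_len` — physical coverage is accounted against
#' the haploid reference length, with fragments split evenly between the
#' two haplotypes — and the excess is then trimmed by keeping a random
#' subset whose total just reaches the per-haplotype target, so the
#' realized coverage is within one fragment length of the target.
#'
#' @param template A `diploid_template`.
#' @param mu_fl Mean fragment length of the exponential shearing (bp).
#' @param c_f Target physical coverage (fold, against the haploid length).
#' @param min_len Minimum retained fragment length (bp).
#' @param seed RNG seed.
#' @return data.table of class `fragment_set`: `fragment_id`, `haplotype`
#'   (1 or 2), `contig`, `start`, `end` (0-based half-open), `len`.
#' @export
shear_fragments <- function(template, mu_fl, c_f, min_len = 1000L,
                            seed = 1L) {
  stopifnot(inherits(template, "diploid_template"))
  if (mu_fl <= min_len || min_len < 1) {
    stop_invalid("need mu_fl > min_len >= 1")
  }
  if (c_f <= 0) stop_invalid("c_f must be positive")
  target <- (c_f / 2) * template$source_len
  contigs <- names(template$contig_lens)
  frags <- with_stage_seed(seed, "shear", {
    per_hap <- lapply(1:2, function(hap) {
      acc <- list()
      total <- 0
      while (total < target) {
        for (ct in contigs) {
          len <- template$contig_lens[[ct]]
          n_draw <- ceiling(len / mu_fl) + ceiling(4 * sqrt(len / mu_fl)) + 10L
          pieces <- rexp(n_draw, rate = 1 / mu_fl)
          ends <- cumsum(pieces)
          while (ends[length(ends)] < len) {
            pieces <- c(pieces, rexp(n_draw, rate = 1 / mu_fl))
            ends <- cumsum(pieces)
          }
          k <- which(ends >= len)[1L]
          ends <- pmin(round(ends[seq_len(k)]), len)
          starts <- c(0, head(ends, -1L))
          ok <- (ends - starts) >= min_len
          if (!any(ok)) next
          acc[[length(acc) + 1L]] <- data.table(
            haplotype = hap, contig = ct,
            start = as.integer(starts[ok]), end = as.integer(ends[ok]))
          total <- total + sum(ends[ok] - starts[ok])
        }
        if (length(acc) == 0L && total == 0 && c_f < 1e-6) break
      }
      dt <- rbindlist(acc)
      if (nrow(dt) == 0L) return(dt)
      ## trim the overshoot: random order, keep the shortest prefix whose
      ## total reaches the per-haplotype target
      dt <- dt[sample(.N)]
      cs <- cumsum(as.numeric(dt$end - dt$start))
      keep_n <- which(cs >= target)[1L]
      if (is.na(keep_n)) keep_n <- nrow(dt)
      dt[seq_len(keep_n)]
    })
    rbindlist(per_hap)
  })
  if (nrow(frags) == 0L) {
    stop_invalid("degenerate shearing: no fragment produced (c_f too small?)")
  }
  frags[, len := end - start]
  frags[, fragment_id := seq_len(.N)]
  setcolorder(frags, c("fragment_id", "haplotype", "contig", "start", "end", "len"))
  setattr(frags, "class", c("fragment_set", class(frags)))
  frags[]
}

#' Allocate fragments to barcoded partitions
#'
#' Partition sizes are drawn from a Poisson(`n_fp`) distribution with zero
#' draws redrawn (a physical partition holds at least one fragment);
#' fragments are assigned in random order without replacement until
#' exhausted, so the last partition may be short. Each partition receives a
#' unique random 16-base barcode. A warning is emitted when the partition
#' count exceeds 4.8 million, the practical barcode limit of the Chromium
#' system.
#'
#' @param fragments A `fragment_set` from [shear_fragments()].
#' @param n_fp Mean fragments per partition.
#' @param seed RNG seed.
#' @param barcode_len Barcode length (bp).
#' @return list of class `partition_set`: `partitions` (data.table of
#'   `partition_id`, `barcode`, `n_fragments`) and `fragments` (the input
#'   with `partition_id` and `barcode` columns added).
#' @export
allocate_partitions <- function(fragments, n_fp, seed = 1L,
                                barcode_len = 16L) {
  if (n_fp <= 0) stop_invalid("n_fp must be positive")
  n <- nrow(fragments)
  if (n == 0L) stop_invalid("empty fragment list")
  with_stage_seed(seed, "partition", {
    sizes <- integer(0)
    while (sum(sizes) < n) {
      draw <- rpois(max(64L, ceiling((n - sum(sizes)) / n_fp * 1.5)), n_fp)
      sizes <- c(sizes, draw[draw > 0L])
    }
    k <- which(cumsum(sizes) >= n)[1L]
    sizes <- sizes[seq_len(k)]
    sizes[k] <- sizes[k] - (sum(sizes) - n)  # last partition may be short
    sizes <- sizes[sizes > 0L]
    k <- length(sizes)
    if (k > 4.8e6) {
      warning(sprintf("%d partitions exceed the 4.8 million barcode limit", k))
    }
    barcodes <- make_unique_barcodes(k, barcode_len)
    assign <- rep.int(seq_len(k), sizes)
    frag_order <- sample.int(n)
    fr <- copy(as.data.table(fragments))
    fr[frag_order, partition_id := assign]
    fr[, barcode := barcodes[partition_id]]
    parts <- fr[, .(n_fragments = .N), by = .(partition_id, barcode)]
    setorder(parts, partition_id)
    structure(list(partitions = parts, fragments = fr),
              class = "partition_set")
  })
}

make_unique_barcodes <- function(k, barcode_len = 16L) {
  gen <- function(m) {
    mat <- matrix(sample(c("A", "C", "G", "T"), m * barcode_len,
                         replace = TRUE), nrow = m)
    apply(mat, 1L, paste, collapse = "")
  }
  bc <- gen(k)
  while (anyDuplicated(bc)) {
    dup <- which(duplicated(bc))
    bc[dup] <- gen(length(dup))
  }
  bc
}

#' @export
print.partition_set <- function(x, ...) {
  cat(sprintf("Partition set: %d partitions, %d fragments (mean %.2f per partition)\n",
              nrow(x$partitions), nrow(x$fragments),
              nrow(x$fragments) / nrow(x$partitions)))
  invisible(x)
}

#' Generate barcoded paired-end reads from partitioned fragments
#'
#' For a fragment of length L the number of read pairs is drawn
#' Poisson(`c_r * L / g`) where `g` is the number of genomic bases per pair
#' (`2 * read_len - 23` under the 16 bp barcode + 7 N spacer layout).
#' Each pair takes an insert length `round(Normal(insert_mean, insert_sd))`
#' clamped to `[2 * read_len, L]` and a uniform start within the fragment.
#' Read 1 is taken from the forward strand of the fragment's haplotype
#' with its first 23 bases overwritten by the partition barcode plus seven
#' Ns; read 2 is the reverse complement of the far end of the insert.
#' Substitution errors are applied i.i.d. at `error_rate` to genomic bases
#' only, and the quality string is the constant Phred score
#' `round(-10 log10(max(error_rate, 1e-4)))`. Fragments shorter than
#' `2 * read_len` are skipped and counted (attribute `skipped_fragments`).
#'
#' @param template A `diploid_template`.
#' @param partitions A `partition_set` from [allocate_partitions()].
#' @param c_r Target read coverage per fragment (fold).
#' @param read_len Read length per end (bp).
#' @param insert_mean,insert_sd Insert-size model (bp).
#' @param error_rate Per-base substitution probability.
#' @param seed RNG seed.
#' @param with_sequences When FALSE, only coordinates and provenance are
#'   generated (fast path for parameter-recovery studies that work from
#'   the truth table).
#' @param barcode_len,n_spacer Barcode/spacer layout (bp).
#' @return data.table of class `read_pair_set`: `read_id`, `barcode`,
#'   `partition_id`, `fragment_id`, `haplotype`, `contig`, `frag_start`,
#'   `frag_end`, `r1_start`, `r2_start`, `insert_len`, and (with
#'   sequences) `r1_seq`, `r2_seq`, `r1_qual`, `r2_qual`. Coordinates are
#'   0-based on the reference contig (identical to haplotype coordinates:
#'   the template has no indels).
#' @export
generate_reads <- function(template, partitions, c_r, read_len = 150L,
                           insert_mean = 500, insert_sd = 50,
                           error_rate = 0, seed = 1L,
                           with_sequences = TRUE,
                           barcode_len = 16L, n_spacer = 7L) {
  stopifnot(inherits(partitions, "partition_set"))
  if (c_r <= 0) stop_invalid("c_r must be positive")
  if (insert_mean < 2 * read_len) {
    stop_invalid("insert_mean must be at least 2 * read_len")
  }
  mask <- as.integer(barcode_len + n_spacer)
  g <- 2L * as.integer(read_len) - mask
  fr <- partitions$fragments
  with_stage_seed(seed, "reads", {
    usable <- fr$len >= 2L * read_len
    n_skipped <- sum(!usable)
    fr_u <- fr[usable == TRUE]
    n_pairs <- rpois(nrow(fr_u), c_r * fr_u$len / g)
    idx <- rep.int(seq_len(nrow(fr_u)), n_pairs)
    reads <- fr_u[idx, .(barcode, partition_id, fragment_id, haplotype,
                         contig, frag_start = start, frag_end = end,
                         len)]
    n <- nrow(reads)
    if (n == 0L) {
      stop_invalid("no read pairs generated (c_r too small for this library?)")
    }
    ins <- as.integer(round(rnorm(n, insert_mean, insert_sd)))
    ins <- pmax(pmin(ins, reads$len), 2L * as.integer(read_len))
    off <- as.integer(floor(runif(n) * (reads$len - ins + 1)))
    reads[, insert_len := ins]
    reads[, r1_start := frag_start + off]
    reads[, r2_start := r1_start + insert_len - as.integer(read_len)]
    reads[, len := NULL]
    reads[, serial := seq_len(.N), by = fragment_id]
    reads[, read_id := sprintf("sim:%d:%d", fragment_id, serial)]
    reads[, serial := NULL]
    if (with_sequences) {
      hapseq <- list(`1` = as_seq_character(template$hap1),
                     `2` = as_seq_character(template$hap2))
      r1 <- character(n)
      r2 <- character(n)
      for (hap in 1:2) {
        for (ct in names(template$contig_lens)) {
          sel <- which(reads$haplotype == hap & reads$contig == ct)
          if (!length(sel)) next
          src <- hapseq[[hap]][[ct]]
          ## r1 genomic tail: bases mask+1 .. read_len of the forward read
          r1[sel] <- substring(src, reads$r1_start[sel] + mask + 1L,
                               reads$r1_start[sel] + read_len)
          r2[sel] <- substring(src, reads$r2_start[sel] + 1L,
                               reads$r2_start[sel] + read_len)
        }
      }
      if (error_rate > 0) {
        r1 <- mutate_strings(r1, error_rate)
        r2 <- mutate_strings(r2, error_rate)
      }
      r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(r2)))
      q <- as.integer(round(-10 * log10(max(error_rate, 1e-4))))
      qchar <- rawToChar(as.raw(q + 33L))
      spacer <- strrep("N", n_spacer)
      reads[, r1_seq := paste0(barcode, spacer, r1)]
      reads[, r2_seq := r2]
      reads[, r1_qual := strrep(qchar, read_len)]
      reads[, r2_qual := strrep(qchar, read_len)]
    }
    setattr(reads, "skipped_fragments", n_skipped)
    setattr(reads, "class", c("read_pair_set", class(reads)))
    reads[]
  })
}

## i.i.d. substitution errors over a character vector of equal-purpose
## sequence strings; N bases are left untouched.
mutate_strings <- function(strs, error_rate) {
  lens <- nchar(strs)
  offsets <- c(0, cumsum(as.numeric(lens)))
  n_tot <- offsets[length(offsets)]
  n_err <- rbinom(1L, as.integer(n_tot), error_rate)
  if (n_err == 0L) return(strs)
  flat <- sort(sample(n_tot, n_err))
  which_str <- findInterval(flat - 0.5, offsets)
  pos_in <- as.integer(flat - offsets[which_str])
  for (s in unique(which_str)) {
    bytes <- charToRaw(strs[s])
    bytes <- substitute_bases(bytes, pos_in[which_str == s])
    strs[s] <- rawToChar(bytes)
  }
  strs
}

#' Write a simulated library as paired FASTQ plus a truth table
#'
#' Writes `<prefix>_R1.fastq.gz` and `<prefix>_R2.fastq.gz` (mate order
#' preserved, matching names) and `<prefix>_truth.tsv`, the alignment-free
#' ground-truth sidecar consumed by the fragment-inference module: columns
#' `read_id`, `barcode`, `partition_id`, `fragment_id`, `haplotype`,
#' `contig`, `frag_start`, `frag_end`, `r1_start`, `r2_start`,
#' `insert_len`.
#'
#' @param reads A `read_pair_set` with sequences.
#' @param out_prefix Output path prefix.
#' @param barcode_sorted Also write `<prefix>_truth.by_barcode.tsv` sorted
#'   by barcode.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_linked_fastq <- function(reads, out_prefix, barcode_sorted = FALSE) {
  if (nrow(reads) == 0L) stop_invalid("empty read stream")
  if (!"r1_seq" %in% names(reads)) {
    stop_invalid("reads carry no sequences; run generate_reads(with_sequences = TRUE)")
  }
  paths <- c(r1 = paste0(out_prefix, "_R1.fastq.gz"),
             r2 = paste0(out_prefix, "_R2.fastq.gz"),
             truth = paste0(out_prefix, "_truth.tsv"))
  write_fastq_gz <- function(path, ids, seqs, quals) {
    con <- gzfile(path, "wb")
    on.exit(close(con))
    writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), con)
  }
  write_fastq_gz(paths[["r1"]], reads$read_id, reads$r1_seq, reads$r1_qual)
  write_fastq_gz(paths[["r2"]], reads$read_id, reads$r2_seq, reads$r2_qual)
  truth_cols <- c("read_id", "barcode", "partition_id", "fragment_id",
                  "haplotype", "contig", "frag_start", "frag_end",
                  "r1_start", "r2_start", "insert_len")
  fwrite(as.data.table(reads)[, ..truth_cols], paths[["truth"]], sep = "\t")
  if (barcode_sorted) {
    p <- paste0(out_prefix, "_truth.by_barcode.tsv")
    tb <- as.data.table(reads)[, ..truth_cols]
    setorder(tb, barcode, contig, r1_start)
    fwrite(tb, p, sep = "\t")
    paths <- c(paths, truth_by_barcode = p)
  }
  invisible(paths)
}

#' Simulate a complete Linked-Read library in one call
#'
#' Convenience wrapper chaining [shear_fragments()],
#' [allocate_partitions()] and [generate_reads()] under per-stage RNG
#' streams derived from `params$seed`.
#'
#' @param template A `diploid_template`.
#' @param params A `library_params` design point.
#' @param min_frag_len Minimum retained sheared fragment length (bp).
#' @param with_sequences Passed to [generate_reads()].
#' @return list of class `simulated_library`: `params`, `fragments`,
#'   `partitions`, `reads`.
#' @export
simulate_library <- function(template, params, min_frag_len = 1000L,
                             with_sequences = TRUE) {
  stopifnot(inherits(params, "library_params"))
  frags <- shear_fragments(template, mu_fl = params$mu_fl, c_f = params$c_f,
                           min_len = min_frag_len, seed = params$seed)
  parts <- allocate_partitions(frags, n_fp = params$n_fp, seed = params$seed,
                               barcode_len = params$barcode_len)
  reads <- generate_reads(template, parts, c_r = params$c_r,
                          read_len = params$read_len,
                          insert_mean = params$insert_mean,
                          insert_sd = params$insert_sd,
                          error_rate = params$error_rate,
                          seed = params$seed,
                          with_sequences = with_sequences,
                          barcode_len = params$barcode_len,
                          n_spacer = params$n_spacer)
  structure(list(params = params, fragments = frags, partitions = parts,
                 reads = reads),
            class = "simulated_library")
}

#' @export
print.simulated_library <- function(x, ...) {
  cat(sprintf("Simulated Linked-Read library: %d fragments, %d partitions, %d read pairs\n",
              nrow(x$fragments), nrow(x$partitions$partitions), nrow(x$reads)))
  print(x$params)
  invisible(x)
}
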