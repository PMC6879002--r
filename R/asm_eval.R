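## Diploid assembly evaluation: scaffold -> contig decomposition at N-gaps,
## N50/NA50 with alignment-based misassembly breaking, windowed
## diploid/haploid genome-fraction classification, chance-overlap
## expectation with a chi-square test, and phase-block statistics on
## maximal diploid runs.

#' Parse a haplotype label from a sequence name
#'
#' Recognised suffixes: `/1`, `/2`, `_hap1`, `_hap2`, optionally followed
#' by a `_ctgN` part (contigs broken out of a labelled scaffold keep the
#' scaffold's label); anything else is `"unphased"`.
#'
#' @param names Character vector of sequence names.
#' @return Character vector over `"1"`, `"2"`, `"unphased"`.
#' @export
parse_haplotype_label <- function(names) {
  out <- rep("unphased", length(names))
  out[grepl("(/1|_hap1)(_ctg[0-9]+)?$", names)] <- "1"
  out[grepl("(/2|_hap2)(_ctg[0-9]+)?$", names)] <- "2"
  out
}

#' Break scaffolds into contigs at N-gaps
#'
#' Each scaffold is split at every maximal run of at least `min_n_run`
#' consecutive N bases (the Supernova-style contig definition); shorter N
#' runs stay inside contigs. Empty pieces are discarded. Offsets and the
#' gap lengths are recorded so the scaffold can be reconstructed exactly.
#'
#' @param scaffolds A [Biostrings::DNAStringSet], named character vector,
#'   or FASTA path.
#' @param min_n_run Minimum N-run length that splits (bp).
#' @return data.table: `name`, `origin_scaffold`, `offset` (0-based start
#'   of the contig within its scaffold), `length`, `haplotype` (parsed
#'   from the scaffold name), `seq`.
#' @export
break_scaffolds <- function(scaffolds, min_n_run = 10L) {
  seqs <- as_seq_character(scaffolds)
  haps <- parse_haplotype_label(names(seqs))
  parts <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    m <- gregexpr(sprintf("N{%d,}", min_n_run), s)[[1L]]
    if (m[1L] == -1L) {
      cuts <- data.table(start = 0L, end = nchar(s))
    } else {
      gap_start <- as.integer(m) - 1L
      gap_end <- gap_start + attr(m, "match.length")
      cuts <- data.table(start = c(0L, gap_end),
                         end = c(gap_start, nchar(s)))
    }
    cuts <- cuts[end > start]
    if (nrow(cuts) == 0L) return(NULL)
    data.table(name = sprintf("%s_ctg%d", names(seqs)[i], seq_len(nrow(cuts))),
               origin_scaffold = names(seqs)[i],
               offset = cuts$start,
               length = cuts$end - cuts$start,
               haplotype = haps[i],
               seq = substring(s, cuts$start + 1L, cuts$end))
  })
  rbindlist(parts)
}

#' Nx contiguity statistic
#'
#' The largest length L such that pieces of length at least L together
#' cover at least x percent of the total; N50 by default. Computed by
#' sorting descending and scanning the cumulative sum.
#'
#' @param lengths Positive piece lengths (bp).
#' @param x Percentage threshold in (0, 100].
#' @return The Nx length (bp).
#' @export
nx <- function(lengths, x = 50) {
  if (length(lengths) == 0L) stop_invalid("empty length list")
  if (any(lengths <= 0) || anyNA(lengths)) {
    stop_invalid("lengths must be positive")
  }
  if (x <= 0 || x > 100) stop_invalid("x must be in (0, 100]")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= x / 100 * sum(s))[1L]]
}

#' Read alignments from a PAF file
#'
#' Parses the 12 standard minimap2 PAF columns; extra columns are ignored.
#'
#' @param path PAF path.
#' @return data.table of class `alignment_blocks`: `qname`, `qlen`,
#'   `qstart`, `qend`, `strand`, `tname`, `tlen`, `tstart`, `tend`,
#'   `n_match`, `aln_len`, `mapq` (coordinates 0-based half-open).
#' @export
read_paf <- function(path) {
  dt <- fread(path, sep = "\t", header = FALSE, fill = TRUE,
              select = 1:12,
              col.names = c("qname", "qlen", "qstart", "qend", "strand",
                            "tname", "tlen", "tstart", "tend", "n_match",
                            "aln_len", "mapq"))
  setattr(dt, "class", c("alignment_blocks", class(dt)))
  dt[]
}

#' Build an alignment-block table from coordinates
#'
#' Convenience constructor for toy evaluations where the assembly derives
#' from the reference with known coordinates (identity alignments).
#'
#' @param qname,qlen,qstart,qend,tname,tstart,tend,strand,mapq Vectors of
#'   block fields; `strand` defaults to `"+"`, `mapq` to 60.
#' @param tlen Target lengths (defaults to `tend`).
#' @return An `alignment_blocks` data.table.
#' @export
alignment_blocks <- function(qname, qlen, qstart, qend, tname, tstart,
                             tend, strand = "+", mapq = 60L, tlen = tend) {
  dt <- data.table(qname = qname, qlen = as.integer(qlen),
                   qstart = as.integer(qstart), qend = as.integer(qend),
                   strand = strand, tname = tname,
                   tlen = as.integer(tlen), tstart = as.integer(tstart),
                   tend = as.integer(tend),
                   n_match = as.integer(qend) - as.integer(qstart),
                   aln_len = as.integer(qend) - as.integer(qstart),
                   mapq = as.integer(mapq))
  setattr(dt, "class", c("alignment_blocks", class(dt)))
  dt[]
}

#' Break query lengths at alignment-detected misassemblies
#'
#' Blocks shorter than `min_block_bp` (query side) or below `min_mapq` are
#' discarded; queries shorter than `min_query_len` are excluded
#' altogether. Within each query, blocks are sorted by query start
#' (query-overlapping blocks resolved by keeping the longer) and a
#' breakpoint is declared between consecutive blocks when (a) the target
#' contigs differ, (b) the strands differ, or (c) the target-side and
#' query-side gaps disagree by more than `max_gap_bp`. The query length is
#' split at the query-side midpoints of the breakpoints. Queries in
#' `query_lengths` with no surviving alignment contribute their full
#' length unbroken (conservative).
#'
#' @param blocks An `alignment_blocks` table.
#' @param query_lengths Named vector of query lengths; defaults to the
#'   `qlen` values present in `blocks`.
#' @param max_gap_bp Tolerated gap disagreement (bp).
#' @param min_block_bp Minimum query-side block length (bp).
#' @param min_mapq Minimum mapping quality.
#' @param min_query_len Minimum query length considered (bp); 500 for
#'   contigs, 1000 for scaffolds.
#' @return Numeric vector of broken piece lengths (bp).
#' @export
break_at_misassemblies <- function(blocks, query_lengths = NULL,
                                   max_gap_bp = 1000L, min_block_bp = 500L,
                                   min_mapq = 0L, min_query_len = 500L) {
  bl <- as.data.table(blocks)
  if (is.null(query_lengths)) {
    ql <- unique(bl[, .(qname, qlen)])
    query_lengths <- stats::setNames(ql$qlen, ql$qname)
  }
  query_lengths <- query_lengths[query_lengths >= min_query_len]
  bl <- bl[(qend - qstart) >= min_block_bp & mapq >= min_mapq &
             qname %in% names(query_lengths)]
  broken <- lapply(names(query_lengths), function(qn) {
    qlen <- query_lengths[[qn]]
    b <- bl[qname == qn]
    if (nrow(b) == 0L) return(qlen)
    setorder(b, qstart, -qend)
    ## resolve query-side overlaps: keep the longer block
    keep <- logical(nrow(b))
    prev_end <- -1L
    prev_i <- NA_integer_
    for (i in seq_len(nrow(b))) {
      if (b$qstart[i] >= prev_end) {
        keep[i] <- TRUE
        prev_end <- b$qend[i]
        prev_i <- i
      } else if ((b$qend[i] - b$qstart[i]) >
                 (b$qend[prev_i] - b$qstart[prev_i])) {
        keep[prev_i] <- FALSE
        keep[i] <- TRUE
        prev_end <- b$qend[i]
        prev_i <- i
      }
    }
    b <- b[keep == TRUE]
    if (nrow(b) <= 1L) return(qlen)
    brk <- integer(0)
    for (i in seq_len(nrow(b) - 1L)) {
      a <- b[i]; d <- b[i + 1L]
      qgap <- d$qstart - a$qend
      tgap <- if (a$strand == "+") d$tstart - a$tend else a$tstart - d$tend
      if (a$tname != d$tname || a$strand != d$strand ||
          abs(tgap - qgap) > max_gap_bp) {
        brk <- c(brk, as.integer(floor((a$qend + d$qstart) / 2)))
      }
    }
    diff(c(0L, brk, qlen))
  })
  as.numeric(unlist(broken))
}

#' Classify reference windows by haplotype-resolved contig coverage
#'
#' The reference is tiled with `window`-bp windows (the last window of a
#' contig may be shorter). A window is covered by a contig when the union
#' of that contig's alignment blocks spans at least `min_cov_frac` of the
#' window. Classes: `diploid` — covered by at least one haplotype-1 and
#' one haplotype-2 contig; `haploid` — covered by exactly one
#' haplotype-labelled contig; `excess` — covered by a single haplotype
#' but more than one of its contigs; `uncovered` — no labelled coverage.
#' Unlabelled contigs count toward overall coverage only (with a
#' warning).
#'
#' @param blocks An `alignment_blocks` table.
#' @param haplotypes Named character vector mapping query name to
#'   `"1"`, `"2"` or `"unphased"`; defaults to
#'   [parse_haplotype_label()] of the query names.
#' @param ref_lens Named numeric vector of reference contig lengths (bp).
#' @param window Window size (bp).
#' @param min_cov_frac Fraction of a window a contig must span to cover it.
#' @return Object of class `window_classification`: list with `windows`
#'   (data.table: `contig`, `win_start`, `win_end`, `class`, `n_hap1`,
#'   `n_hap2`, `covered_any`), `fractions` (named vector: overall,
#'   diploid, haploid, excess, uncovered), `window`, `ref_lens`.
#' @export
classify_windows <- function(blocks, ref_lens, haplotypes = NULL,
                             window = 500L, min_cov_frac = 1.0) {
  bl <- as.data.table(blocks)
  qn_all <- unique(bl$qname)
  if (is.null(haplotypes)) {
    haplotypes <- stats::setNames(parse_haplotype_label(qn_all), qn_all)
  }
  ## queries missing from the supplied map are unphased
  missing_q <- setdiff(qn_all, names(haplotypes))
  if (length(missing_q)) {
    haplotypes <- c(haplotypes,
                    stats::setNames(rep("unphased", length(missing_q)),
                                    missing_q))
  }
  if (any(haplotypes[qn_all] == "unphased")) {
    warning("unlabelled contigs present; counted toward overall coverage only")
  }
  win_list <- lapply(names(ref_lens), function(ct) {
    len <- ref_lens[[ct]]
    starts <- seq(0L, len - 1L, by = window)
    data.table(contig = ct, win_start = as.integer(starts),
               win_end = as.integer(pmin(starts + window, len)))
  })
  wins <- rbindlist(win_list)
  wins[, n_hap1 := 0L]
  wins[, n_hap2 := 0L]
  wins[, covered_any := FALSE]
  for (ct in names(ref_lens)) {
    wsel <- which(wins$contig == ct)
    if (!length(wsel)) next
    wir <- IRanges::IRanges(start = wins$win_start[wsel] + 1L,
                            end = wins$win_end[wsel])
    b_ct <- bl[tname == ct]
    if (nrow(b_ct) == 0L) next
    for (qn in unique(b_ct$qname)) {
      qb <- b_ct[qname == qn]
      qir <- IRanges::reduce(IRanges::IRanges(start = qb$tstart + 1L,
                                              end = qb$tend))
      cov <- IRanges::coverage(qir, width = ref_lens[[ct]])
      covered_w <- vapply(seq_along(wir), function(i) {
        sum(as.integer(
          IRanges::Views(cov, IRanges::start(wir)[i],
                         IRanges::end(wir)[i])[[1L]] > 0L))
      }, integer(1))
      full <- covered_w >= min_cov_frac * IRanges::width(wir)
      hap <- haplotypes[[qn]] %||% "unphased"
      if (hap == "1") {
        wins$n_hap1[wsel[full]] <- wins$n_hap1[wsel[full]] + 1L
      } else if (hap == "2") {
        wins$n_hap2[wsel[full]] <- wins$n_hap2[wsel[full]] + 1L
      }
      wins$covered_any[wsel[full]] <- TRUE
    }
  }
  wins[, class_ := fifelse(n_hap1 >= 1L & n_hap2 >= 1L, "diploid",
                   fifelse(n_hap1 + n_hap2 == 1L, "haploid",
                   fifelse(n_hap1 + n_hap2 >= 2L, "excess", "uncovered")))]
  setnames(wins, "class_", "class")
  n <- nrow(wins)
  fractions <- c(overall = mean(wins$covered_any),
                 diploid = mean(wins$class == "diploid"),
                 haploid = mean(wins$class == "haploid"),
                 excess = mean(wins$class == "excess"),
                 uncovered = mean(wins$class == "uncovered"))
  structure(list(windows = wins, fractions = fractions, window = window,
                 ref_lens = ref_lens),
            class = "window_classification")
}

#' @export
print.window_classification <- function(x, ...) {
  cat(sprintf("Window classification (%d bp windows, %d windows)\n",
              x$window, nrow(x$windows)))
  f <- x$fractions * 100
  cat(sprintf("  overall %.1f%%, diploid %.1f%%, haploid %.1f%%, excess %.1f%%, uncovered %.1f%%\n",
              f[["overall"]], f[["diploid"]], f[["haploid"]],
              f[["excess"]], f[["uncovered"]]))
  invisible(x)
}

#' Maximal diploid regions from a window classification
#'
#' Merges maximal runs of consecutive diploid windows per reference
#' contig.
#'
#' @param classification A `window_classification`.
#' @return data.table: `contig`, `start`, `end`, `len` (0-based
#'   half-open), BED-compatible.
#' @export
diploid_regions <- function(classification) {
  w <- classification$windows
  dip <- w[class == "diploid"]
  if (nrow(dip) == 0L) {
    return(data.table(contig = character(), start = integer(),
                      end = integer(), len = integer()))
  }
  setorder(dip, contig, win_start)
  dip[, run_id := cumsum(c(TRUE, win_start[-1L] != win_end[-.N])),
      by = contig]
  out <- dip[, .(start = min(win_start), end = max(win_end)),
             by = .(contig, run_id)]
  out[, run_id := NULL]
  out[, len := end - start]
  out[]
}

#' Expected chance overlap of diploid fractions
#'
#' Under independence, the expected fraction of the genome diploid in all
#' assemblies simultaneously is the product of the per-assembly diploid
#' fractions.
#'
#' @param fractions Numeric vector of fractions in `[0, 1]`.
#' @return The product.
#' @examples
#' chance_overlap(c(0.589, 0.733, 0.772)) * 100  # ~33.3
#' @export
chance_overlap <- function(fractions) {
  if (length(fractions) == 0L || any(fractions < 0) || any(fractions > 1) ||
      anyNA(fractions)) {
    stop_invalid("fractions must lie in [0, 1]")
  }
  prod(fractions)
}

#' Chi-square test of observed vs chance overlap
#'
#' One-degree-of-freedom goodness-of-fit comparing
#' `(observed, total - observed)` window counts against the chance
#' expectation `(total * p, total * (1 - p))`.
#'
#' @param observed Number of windows diploid in all assemblies.
#' @param total Total number of windows.
#' @param expected_fraction Chance expectation `p`, in (0, 1).
#' @return list: `statistic`, `p_value`, `df`, `low_expected` (TRUE when
#'   any expected count is below 5).
#' @export
overlap_chi2 <- function(observed, total, expected_fraction) {
  if (expected_fraction <= 0 || expected_fraction >= 1) {
    stop_invalid("expected_fraction must lie in (0, 1)")
  }
  if (observed < 0 || observed > total) {
    stop_invalid("need 0 <= observed <= total")
  }
  e <- c(total * expected_fraction, total * (1 - expected_fraction))
  o <- c(observed, total - observed)
  stat <- sum((o - e)^2 / e)
  list(statistic = stat,
       p_value = pchisq(stat, df = 1L, lower.tail = FALSE),
       df = 1L,
       low_expected = any(e < 5))
}

#' Assembly diploid-coverage report
#'
#' Summarises an assembly the way diploid-coverage tables are usually
#' presented: total contig length (contigs above `min_contig_len` only),
#' length and percentage of haplotype-labelled contigs, and — when a
#' window classification is supplied — overall/diploid/haploid genome
#' fractions, plus the haploid ("covered by exactly one contig") fraction
#' of an optional designated region set such as the non-pseudoautosomal X.
#'
#' @param contigs data.table with `length` and `haplotype` columns (e.g.
#'   from [break_scaffolds()]).
#' @param classification Optional `window_classification`.
#' @param designated_regions Optional data.table of `contig`, `start`,
#'   `end` (0-based half-open) regions whose haploid fraction is reported.
#' @param min_contig_len Minimum contig length counted (bp).
#' @return list of class `diploid_report`.
#' @export
diploid_length_report <- function(contigs, classification = NULL,
                                  designated_regions = NULL,
                                  min_contig_len = 500L) {
  ct <- as.data.table(contigs)[length > min_contig_len]
  total_len <- sum(as.numeric(ct$length))
  labeled_len <- sum(as.numeric(ct[haplotype %in% c("1", "2")]$length))
  out <- list(total_contig_length = total_len,
              labeled_contig_length = labeled_len,
              labeled_percentage = 100 * labeled_len / total_len)
  if (!is.null(classification)) {
    f <- classification$fractions
    out$overall_pct <- 100 * f[["overall"]]
    out$diploid_pct <- 100 * f[["diploid"]]
    out$haploid_pct <- 100 * f[["haploid"]]
    if (!is.null(designated_regions)) {
      w <- classification$windows
      dr <- as.data.table(designated_regions)
      sel <- rep(FALSE, nrow(w))
      for (i in seq_len(nrow(dr))) {
        sel <- sel | (w$contig == dr$contig[i] &
                        w$win_start >= dr$start[i] &
                        w$win_end <= dr$end[i])
      }
      out$designated_haploid_pct <- 100 * mean(w$class[sel] == "haploid")
    }
  }
  structure(out, class = "diploid_report")
}

#' @export
print.diploid_report <- function(x, ...) {
  cat("Diploid assembly report\n")
  cat(sprintf("  total contig length:   %s bp\n",
              format(x$total_contig_length, big.mark = ",")))
  cat(sprintf("  haplotype-labelled:    %s bp (%.2f%%)\n",
              format(x$labeled_contig_length, big.mark = ","),
              x$labeled_percentage))
  if (!is.null(x$overall_pct)) {
    cat(sprintf("  genome fractions: overall %.1f%%, diploid %.1f%%, haploid %.1f%%\n",
                x$overall_pct, x$diploid_pct, x$haploid_pct))
  }
  if (!is.null(x$designated_haploid_pct)) {
    cat(sprintf("  designated regions haploid: %.1f%%\n",
                x$designated_haploid_pct))
  }
  invisible(x)
}

#' Phase-block N50 from maximal diploid runs
#'
#' Phase blocks are operationalised as the maximal runs of consecutive
#' diploid windows; their N50 is computed with [nx()].
#'
#' @param classification A `window_classification`.
#' @return N50 of diploid-run lengths (bp).
#' @export
phase_block_n50 <- function(classification) {
  runs <- diploid_regions(classification)
  if (nrow(runs) == 0L) stop_invalid("no diploid windows")
  nx(runs$len, 50)
}
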