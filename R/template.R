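## Diploid template construction: duplicate a reference into two haplotypes
## and insert SNVs — supplied calls inside high-confidence regions, random
## SNVs at a fixed density elsewhere. SNV-only divergence: both haplotypes
## keep the reference length, so haplotype and reference coordinates agree.

#' Build a diploid template genome from a reference
#'
#' Duplicates the reference into two haplotypes and inserts single
#' nucleotide variants. Supplied calls (typically from a high-confidence
#' benchmark set) are inserted with their stated zygosity. Everywhere
#' outside the high-confidence regions (or everywhere, when no regions are
#' given) random SNVs are placed per-base Bernoulli at `lc_density` sites
#' per kb, with heterozygous:homozygous zygosity drawn at
#' `het_hom_ratio`:1 (default 2:1) and the heterozygous haplotype chosen by
#' fair coin. The alternate allele is uniform over the three non-reference
#' bases; reference N bases are never mutated.
#'
#' @param reference A [Biostrings::DNAStringSet], named character vector,
#'   FASTA path, or `synthetic_reference`.
#' @param hc_regions High-confidence intervals: a
#'   [GenomicRanges::GRanges], a BED path (0-based half-open), or NULL.
#'   Overlapping intervals are merged.
#' @param snv_calls Supplied SNV calls: a data.frame with columns
#'   `contig`, `pos` (0-based), `ref`, `alt`, `zygosity`
#'   (`"het_hap1"`, `"het_hap2"`, `"hom"`), a VCF path, or NULL.
#' @param lc_density Random SNV density outside high-confidence regions,
#'   sites per kb.
#' @param het_hom_ratio Ratio of heterozygous to homozygous random SNVs.
#' @param seed RNG seed.
#' @return An object of class `diploid_template`: list with `hap1` and
#'   `hap2` ([Biostrings::DNAStringSet]), `snv_table` (data.table of
#'   `contig`, `pos`, `ref`, `alt`, `zygosity`), `source_len` (total
#'   reference bp) and `contig_lens` (named integer vector).
#' @export
build_template <- function(reference, hc_regions = NULL, snv_calls = NULL,
                           lc_density = 1.0, het_hom_ratio = 2.0,
                           seed = 1L) {
  if (inherits(reference, "synthetic_reference")) reference <- reference$sequences
  seqs <- as_seq_character(reference)
  if (length(seqs) == 0L || sum(nchar(seqs)) == 0L) {
    stop_invalid("reference is empty")
  }
  if (lc_density < 0) stop_invalid("lc_density must be non-negative")
  if (het_hom_ratio <= 0) stop_invalid("het_hom_ratio must be positive")
  contig_lens <- nchar(seqs)
  hc <- normalize_hc_regions(hc_regions, contig_lens)
  supplied <- normalize_snv_calls(snv_calls, seqs, seed)

  snv_table <- with_stage_seed(seed, "template", {
    p <- lc_density / 1000
    p_hom <- 1 / (1 + het_hom_ratio)
    random_parts <- lapply(names(seqs), function(ct) {
      len <- contig_lens[[ct]]
      eligible <- rep(TRUE, len)
      bytes <- charToRaw(seqs[[ct]])
      eligible[bytes == charToRaw("N")] <- FALSE
      if (!is.null(hc)) {
        hci <- hc[GenomicRanges::seqnames(hc) == ct]
        for (i in seq_along(hci)) {
          eligible[GenomicRanges::start(hci)[i]:GenomicRanges::end(hci)[i]] <- FALSE
        }
      }
      if (!is.null(supplied) && nrow(supplied)) {
        eligible[supplied[contig == ct, pos] + 1L] <- FALSE
      }
      if (p <= 0) return(NULL)
      hit <- which(runif(len) < p & eligible)
      if (!length(hit)) return(NULL)
      ref_b <- rawToChar(bytes[hit], multiple = TRUE)
      alt_b <- vapply(ref_b, function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1), USE.NAMES = FALSE)
      zyg <- ifelse(runif(length(hit)) < p_hom, "hom",
                    ifelse(runif(length(hit)) < 0.5, "het_hap1", "het_hap2"))
      data.table(contig = ct, pos = hit - 1L, ref = ref_b, alt = alt_b,
                 zygosity = zyg)
    })
    rbindlist(c(list(supplied), random_parts))
  })
  if (nrow(snv_table)) {
    setorder(snv_table, contig, pos)
    if (anyDuplicated(snv_table, by = c("contig", "pos"))) {
      stop_invalid("duplicate SNV records at the same (contig, position)")
    }
  }
  haps <- apply_snv_table(seqs, snv_table)
  structure(
    list(hap1 = Biostrings::DNAStringSet(haps$hap1),
         hap2 = Biostrings::DNAStringSet(haps$hap2),
         snv_table = snv_table,
         source_len = sum(contig_lens),
         contig_lens = contig_lens),
    class = "diploid_template"
  )
}

#' Apply an SNV table to a reference, producing two haplotypes
#'
#' The exact inverse relationship used by [build_template()]: homozygous
#' records place the alternate allele on both haplotypes, `het_hapK`
#' records on haplotype K only.
#'
#' @param reference Sequences (any form accepted by [build_template()]).
#' @param snv_table data.table/data.frame with `contig`, `pos` (0-based),
#'   `ref`, `alt`, `zygosity`.
#' @return list with named character vectors `hap1` and `hap2`.
#' @export
apply_snv_table <- function(reference, snv_table) {
  seqs <- as_seq_character(reference)
  snv_table <- as.data.table(snv_table)
  hap1 <- seqs
  hap2 <- seqs
  if (nrow(snv_table)) {
    for (ct in unique(snv_table$contig)) {
      recs <- snv_table[contig == ct]
      b1 <- charToRaw(seqs[[ct]])
      b2 <- b1
      at <- recs$pos + 1L
      cur <- rawToChar(b1[at], multiple = TRUE)
      if (!all(cur == recs$ref)) {
        stop_invalid("SNV ref allele mismatches the reference on %s", ct)
      }
      altraw <- vapply(recs$alt, function(a) charToRaw(a), raw(1),
                       USE.NAMES = FALSE)
      on1 <- recs$zygosity %in% c("hom", "het_hap1")
      on2 <- recs$zygosity %in% c("hom", "het_hap2")
      b1[at[on1]] <- altraw[on1]
      b2[at[on2]] <- altraw[on2]
      hap1[[ct]] <- rawToChar(b1)
      hap2[[ct]] <- rawToChar(b2)
    }
  }
  list(hap1 = hap1, hap2 = hap2)
}

normalize_hc_regions <- function(hc_regions, contig_lens) {
  if (is.null(hc_regions)) return(NULL)
  if (is_string(hc_regions)) {
    hc_regions <- rtracklayer::import(hc_regions, format = "BED")
  }
  if (!methods::is(hc_regions, "GRanges")) {
    stop_invalid("hc_regions must be NULL, a BED path, or a GRanges")
  }
  hc <- GenomicRanges::reduce(hc_regions)
  for (ct in unique(as.character(GenomicRanges::seqnames(hc)))) {
    if (!ct %in% names(contig_lens)) {
      stop_invalid("hc_regions contig '%s' not in the reference", ct)
    }
    if (max(GenomicRanges::end(hc[GenomicRanges::seqnames(hc) == ct])) >
        contig_lens[[ct]]) {
      stop_invalid("hc_regions extend past the end of contig '%s'", ct)
    }
  }
  hc
}

normalize_snv_calls <- function(snv_calls, seqs, seed) {
  if (is.null(snv_calls)) {
    return(data.table(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      zygosity = character()))
  }
  if (is_string(snv_calls)) snv_calls <- read_snv_vcf(snv_calls, seed = seed)
  calls <- as.data.table(snv_calls)
  need <- c("contig", "pos", "ref", "alt", "zygosity")
  if (!all(need %in% names(calls))) {
    stop_invalid("snv_calls must have columns %s", paste(need, collapse = ", "))
  }
  calls <- calls[, ..need]
  calls[, pos := as.integer(pos)]
  bad_z <- setdiff(unique(calls$zygosity), c("het_hap1", "het_hap2", "hom"))
  if (length(bad_z)) stop_invalid("unknown zygosity value(s): %s",
                                  paste(bad_z, collapse = ", "))
  for (ct in unique(calls$contig)) {
    if (!ct %in% names(seqs)) {
      stop_invalid("snv_calls contig '%s' not in the reference", ct)
    }
    recs <- calls[contig == ct]
    obs <- rawToChar(charToRaw(seqs[[ct]])[recs$pos + 1L], multiple = TRUE)
    if (!all(obs == recs$ref)) {
      stop_invalid("supplied call ref allele mismatches the reference on %s", ct)
    }
  }
  calls
}

#' Write diploid template haplotypes as FASTA
#'
#' Contig names gain `_hap1` / `_hap2` suffixes.
#'
#' @param template A `diploid_template`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_template_fasta <- function(template, path) {
  h1 <- template$hap1
  h2 <- template$hap2
  names(h1) <- paste0(names(h1), "_hap1")
  names(h2) <- paste0(names(h2), "_hap2")
  Biostrings::writeXStringSet(c(h1, h2), path)
  invisible(path)
}

#' Write a template SNV table as VCF 4.2
#'
#' Phased genotypes: `het_hap1` becomes `1|0`, `het_hap2` `0|1`, `hom`
#' `1|1`. Positions convert to VCF's 1-based convention.
#'
#' @param template A `diploid_template` (or anything with a `snv_table`).
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(template, path) {
  tab <- as.data.table(template$snv_table)
  gt <- c(het_hap1 = "1|0", het_hap2 = "0|1", hom = "1|1")[tab$zygosity]
  hdr <- c("##fileformat=VCFv4.2",
           "##source=lrkit",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           sprintf("##contig=<ID=%s,length=%d>",
                   names(template$contig_lens), template$contig_lens),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                  tab$contig, tab$pos + 1L, tab$ref, tab$alt, gt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read SNV calls from a VCF file
#'
#' Keeps biallelic SNVs with a GT field. Phased heterozygotes map `1|0`
#' to haplotype 1 and `0|1` to haplotype 2; unphased heterozygotes
#' (`0/1`, `1/0`) are assigned a haplotype by fair coin under `seed`.
#'
#' @param path VCF path.
#' @param seed RNG seed used only for unphased heterozygote assignment.
#' @return data.table with `contig`, `pos` (0-based), `ref`, `alt`,
#'   `zygosity`.
#' @export
read_snv_vcf <- function(path, seed = 1L) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.table(vcfR::getFIX(v))
  gt <- vcfR::extract.gt(v, element = "GT")[, 1L]
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L & !is.na(gt) &
    fix$ALT %in% c("A", "C", "G", "T")
  fix <- fix[keep == TRUE]
  gt <- gt[keep]
  zyg <- with_stage_seed(seed, "vcf_phase", {
    vapply(gt, function(g) {
      switch(g,
             "1|0" = "het_hap1",
             "0|1" = "het_hap2",
             "1|1" = "hom",
             "1/1" = "hom",
             "0/1" = ,
             "1/0" = if (runif(1) < 0.5) "het_hap1" else "het_hap2",
             NA_character_)
    }, character(1), USE.NAMES = FALSE)
  })
  out <- data.table(contig = fix$CHROM, pos = as.integer(fix$POS) - 1L,
                    ref = fix$REF, alt = fix$ALT, zygosity = zyg)
  out[!is.na(zygosity)]
}

#' @export
print.diploid_template <- function(x, ...) {
  cat(sprintf("Diploid template: %d contig(s), %s bp haploid, %d SNV(s)\n",
              length(x$hap1), format(x$source_len, big.mark = ","),
              nrow(x$snv_table)))
  if (nrow(x$snv_table)) {
    z <- table(x$snv_table$zygosity)
    cat("  zygosity: ", paste(names(z), z, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
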