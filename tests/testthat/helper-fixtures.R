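## Shared fixture builders. Everything is generated in code at test time;
## no binary fixtures.

suppressMessages(library(data.table))

make_template <- function(contig_len = 100000L, n_contigs = 1L, seed = 1L,
                          lc_density = 1.0, gc = 0.41) {
  spec <- synthetic_reference_spec(n_contigs = n_contigs,
                                   contig_len = contig_len,
                                   gc_content = gc, seed = seed)
  build_template(generate_reference(spec), lc_density = lc_density,
                 seed = seed)
}

## A partition_set wrapping explicitly constructed fragments, for read
## generation tests that need exact fragment geometry.
make_partition_set <- function(fragments, barcodes = NULL) {
  fr <- as.data.table(fragments)
  if (!"partition_id" %in% names(fr)) fr[, partition_id := seq_len(.N)]
  if (is.null(barcodes)) {
    barcodes <- vapply(seq_len(max(fr$partition_id)), function(i) {
      paste(rep(c("A", "C", "G", "T"), 4)[seq_len(16)], collapse = "")
    }, character(1))
    ## make them unique by mutating a suffix
    barcodes <- paste0(substr(barcodes, 1, 12),
                       c("AAAA", "CCCC", "GGGG", "TTTT",
                         "ACGT", "TGCA", "GATC", "CTAG")[
                           ((seq_along(barcodes) - 1L) %% 8L) + 1L])
  }
  fr[, barcode := barcodes[partition_id]]
  if (!"len" %in% names(fr)) fr[, len := end - start]
  parts <- fr[, .(n_fragments = .N), by = .(partition_id, barcode)]
  structure(list(partitions = parts, fragments = fr),
            class = "partition_set")
}

## Placement table helper: one row per read pair.
make_placements <- function(barcode, leftmost, rightmost,
                            contig = "contig1") {
  data.table(read_id = sprintf("r%d", seq_along(leftmost)),
             barcode = barcode, contig = contig,
             leftmost = as.numeric(leftmost),
             rightmost = as.numeric(rightmost))
}

as_char <- function(x) {
  out <- as.character(x)
  names(out) <- names(x)
  out
}

## Independent template oracle: undo the alt alleles carried by hap1/hap2
## to recover the source reference sequence.
reconstruct_reference <- function(tpl) {
  seqs <- as_char(tpl$hap1)
  tab <- as.data.table(tpl$snv_table)
  for (ct in unique(tab$contig)) {
    recs <- tab[contig == ct & zygosity %in% c("hom", "het_hap1")]
    if (nrow(recs) == 0L) next
    bytes <- charToRaw(seqs[[ct]])
    bytes[recs$pos + 1L] <- vapply(recs$ref, charToRaw, raw(1),
                                   USE.NAMES = FALSE)
    seqs[[ct]] <- rawToChar(bytes)
  }
  seqs
}

## Brute-force Nx oracle: scan every candidate threshold.
nx_oracle <- function(lengths, x = 50) {
  total <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(lengths[lengths >= L]) >= x / 100 * total) return(L)
  }
  min(lengths)
}
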