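## Synthetic reference generation: random contigs at a target GC content,
## optionally with planted copies of a fixed repeat unit as a stand-in for
## interspersed repeats.

#' Specification for a synthetic reference genome
#'
#' @param n_contigs Number of contigs.
#' @param contig_len Length of each contig (bp).
#' @param gc_content Target GC fraction, in (0, 1).
#' @param repeat_unit_len Length of the planted repeat unit (bp); ignored
#'   when `repeat_copies` is 0.
#' @param repeat_copies Total number of repeat copies to plant across the
#'   genome; 0 disables repeat planting.
#' @param seed RNG seed.
#' @return An object of class `synthetic_reference_spec`.
#' @export
synthetic_reference_spec <- function(n_contigs = 1L, contig_len = 100000L,
                                     gc_content = 0.41,
                                     repeat_unit_len = 300L,
                                     repeat_copies = 0L, seed = 1L) {
  if (contig_len <= 0) stop_invalid("contig_len must be positive")
  if (gc_content <= 0 || gc_content >= 1) stop_invalid("gc_content must be in (0,1)")
  if (repeat_copies < 0 || repeat_unit_len <= 0) {
    stop_invalid("repeat settings must be non-negative / positive")
  }
  structure(list(n_contigs = as.integer(n_contigs),
                 contig_len = as.integer(contig_len),
                 gc_content = gc_content,
                 repeat_unit_len = as.integer(repeat_unit_len),
                 repeat_copies = as.integer(repeat_copies),
                 seed = as.integer(seed)),
            class = "synthetic_reference_spec")
}

#' Generate a synthetic reference genome
#'
#' Draws each contig i.i.d. at the requested GC content. When
#' `repeat_copies > 0`, a single random repeat unit is generated once and
#' planted at random non-overlapping positions across the genome; the
#' placements are returned as an annotation table so downstream analyses
#' (e.g. repeat masking experiments) can recover them. Deterministic under
#' the spec seed.
#'
#' @param spec A `synthetic_reference_spec`.
#' @return A list of class `synthetic_reference` with elements
#'   `sequences` (a named [Biostrings::DNAStringSet]) and `repeats`
#'   (a data.table of `contig`, `start`, `end`, 0-based half-open).
#' @export
generate_reference <- function(spec) {
  stopifnot(inherits(spec, "synthetic_reference_spec"))
  with_stage_seed(spec$seed, "reference", {
    seqs <- vapply(seq_len(spec$n_contigs), function(i) {
      random_dna(spec$contig_len, spec$gc_content)
    }, character(1))
    names(seqs) <- paste0("contig", seq_len(spec$n_contigs))
    repeats <- data.table(contig = character(), start = integer(),
                          end = integer())
    if (spec$repeat_copies > 0L) {
      unit <- random_dna(spec$repeat_unit_len, spec$gc_content)
      ## distribute copies over contigs proportional to length (equal here)
      copy_contig <- sample(seq_len(spec$n_contigs), spec$repeat_copies,
                            replace = TRUE)
      placements <- vector("list", spec$n_contigs)
      for (ci in seq_len(spec$n_contigs)) {
        k <- sum(copy_contig == ci)
        if (k == 0L) next
        max_start <- spec$contig_len - spec$repeat_unit_len
        if (max_start < 0L) stop_invalid("repeat unit longer than contig")
        starts <- integer(0)
        tries <- 0L
        while (length(starts) < k) {
          cand <- sample.int(max_start + 1L, 1L) - 1L
          if (!any(abs(cand - starts) < spec$repeat_unit_len)) {
            starts <- c(starts, cand)
          }
          tries <- tries + 1L
          if (tries > 1000L * k) {
            stop_invalid("could not place %d non-overlapping repeat copies", k)
          }
        }
        placements[[ci]] <- data.table(contig = names(seqs)[ci],
                                       start = as.integer(sort(starts)),
                                       end = as.integer(sort(starts)) +
                                         spec$repeat_unit_len)
        bytes <- charToRaw(seqs[ci])
        ubytes <- charToRaw(unit)
        for (s in starts) bytes[(s + 1L):(s + spec$repeat_unit_len)] <- ubytes
        seqs[ci] <- rawToChar(bytes)
      }
      repeats <- rbindlist(placements)
    }
    structure(list(sequences = Biostrings::DNAStringSet(seqs),
                   repeats = repeats,
                   spec = spec),
              class = "synthetic_reference")
  })
}

#' @export
print.synthetic_reference <- function(x, ...) {
  cat(sprintf("Synthetic reference: %d contig(s), %s bp total, %d planted repeat(s)\n",
              length(x$sequences),
              format(sum(Biostrings::width(x$sequences)), big.mark = ","),
              nrow(x$repeats)))
  invisible(x)
}
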