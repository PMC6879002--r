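## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific RNG seed from a master seed
#'
#' Each pipeline stage (reference generation, template construction,
#' shearing, partition allocation, read generation, subsampling) draws from
#' its own stream derived from the master seed and a stable stage name, so
#' changing one stage's parameters does not perturb another stage's draws.
#' The result always lies in `[1, 2^31 - 2]`.
#'
#' @param seed Integer master seed.
#' @param stage Character stage name.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  s <- (abs(as.numeric(seed)) %% 2147483647) * 48271 + h * 69621
  as.integer(s %% 2147483646) + 1L
}

with_stage_seed <- function(seed, stage, code) {
  withr::with_seed(stage_seed(seed, stage), code)
}

## Random DNA string(s) of given lengths at a target GC content.
random_dna <- function(n, gc = 0.5) {
  at <- (1 - gc) / 2
  bases <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
                  prob = c(at, gc / 2, gc / 2, at))
  paste(bases, collapse = "")
}

## Substitute bases at 1-based positions `at` in raw byte vector `bytes`
## with a uniformly chosen different base (A/C/G/T only; N untouched).
substitute_bases <- function(bytes, at) {
  acgt <- charToRaw("ACGT")
  cur <- bytes[at]
  ok <- cur %in% acgt
  at <- at[ok]
  if (!length(at)) return(bytes)
  cur <- bytes[at]
  repl <- acgt[sample.int(3L, length(at), replace = TRUE)]
  ## shift any draw that hit the current base to the remaining 4th base
  clash <- repl == cur
  if (any(clash)) {
    for (i in which(clash)) {
      others <- acgt[acgt != cur[i]]
      repl[i] <- others[3L]
    }
  }
  bytes[at] <- repl
  bytes
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

## Coerce a DNAStringSet / named character vector / FASTA path to a named
## character vector of sequences.
as_seq_character <- function(x) {
  if (is_string(x) && file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (methods::is(x, "DNAStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x) %||% paste0("seq", seq_along(x)))
    return(out)
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(x)
  }
  stop_invalid("cannot interpret object of class '%s' as sequences", class(x)[1])
}
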