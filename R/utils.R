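# small shared helpers

DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA string
#' @keywords internal
.randomDna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of a plain character string
#' @keywords internal
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Mutate a DNA string at a given per-base substitution rate
#' @keywords internal
.mutateDna <- function(x, rate) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(DNA_BASES, b), 1L),
                      character(1))
  }
  paste(ch, collapse = "")
}

# coerce DNAStringSet / DNAString / character to named character vector
.asSeqChar <- function(x) {
  if (is(x, "DNAStringSet")) {
    out <- as.character(x)
  } else if (is(x, "DNAString")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- x
  } else {
    stop("expected character, DNAString or DNAStringSet")
  }
  toupper(out)
}

.stopifnot_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lo, hi))
  invisible(x)
}
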