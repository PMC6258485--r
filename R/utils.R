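# Internal helpers shared across modules.

#' Reverse complement of DNA strings
#'
#' Vectorized reverse complement over the ACGTN alphabet.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of the same length.
#' @keywords internal
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' @keywords internal
gc_fraction <- function(x) {
  n_gc <- nchar(gsub("[^GCgc]", "", x))
  n_gc / nchar(x)
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. `seed = NULL` uses the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a reproducible child seed below 2^31 from a parent seed and a tag.
child_seed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000003L) * 1997L + sum(utf8ToInt(as.character(tag))) %% 99991L
}

stopifnot_dna <- function(x, what = "sequence", alphabet = "ACGT") {
  bad <- grepl(sprintf("[^%s]", alphabet), x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside %s: %s",
                 what, alphabet, x[which(bad)[1]]), call. = FALSE)
  }
  invisible(x)
}

# Collapse a character vector to a single comma-joined token ("" if empty).
join_csv <- function(x) {
  if (length(x) == 0) "" else paste(x, collapse = ",")
}

split_csv <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ",", fixed = TRUE)[[1]]
}
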