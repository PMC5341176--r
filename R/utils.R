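# Shared low-level helpers: seeded evaluation, TSV IO, base62 keys, formatting.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are pure functions of their
#' arguments and never perturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# TSV conventions: UTF-8, tab-delimited, headered, no quoting (fixture fields
# never contain tabs), NA written as empty string.
read_tsv_file <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
             na.strings = NULL, quote = "", comment.char = "",
             check.names = FALSE, fileEncoding = "UTF-8")
}

write_tsv_file <- function(df, path) {
  df <- as.data.frame(df)
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.logical(v)) v <- ifelse(v, "TRUE", "FALSE")
    df[[nm]] <- ifelse(is.na(v), "", as.character(v))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, useBytes = TRUE)
  if (nrow(df) > 0) {
    lines <- do.call(paste, c(unname(as.list(df)), sep = "\t"))
    writeLines(lines, con, useBytes = TRUE)
  }
  invisible(path)
}

BASE62_ALPHABET <- c(0:9, LETTERS, letters)

#' Render a nonnegative integer counter in base62 over [0-9A-Za-z]
#' @noRd
base62_encode <- function(n) {
  n <- as.numeric(n)
  stopifnot(n >= 0, n == floor(n))
  if (n == 0) return("0")
  out <- character(0)
  while (n > 0) {
    out <- c(BASE62_ALPHABET[(n %% 62) + 1], out)
    n <- n %/% 62
  }
  paste(out, collapse = "")
}

base62_decode <- function(key) {
  chars <- strsplit(key, "")[[1]]
  vals <- match(chars, BASE62_ALPHABET) - 1
  if (anyNA(vals)) stop("not a base62 key: ", key, call. = FALSE)
  sum(vals * 62^(rev(seq_along(vals)) - 1))
}

#' One-decimal percentage with round-half-even, as number and display string
#'
#' Zero denominators render as an em dash rather than 0 (the percentage is
#' undefined, not zero).
#' @noRd
pct_one_decimal <- function(numerator, denominator) {
  if (denominator == 0) {
    list(pct = NA_real_, display = "—")
  } else {
    p <- round(100 * numerator / denominator, 1)
    list(pct = p, display = sprintf("%.1f%%", p))
  }
}

# Deterministic pseudo-words for fixture names: alternating consonant/vowel
# syllables drawn from the active RNG stream.
random_word <- function(n_syllables = 3) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  paste0(paste0(sample(cons, n_syllables, replace = TRUE),
                sample(vow, n_syllables, replace = TRUE)), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Empty prototypes used so freshly created stores have fully typed tables.
empty_df <- function(...) {
  spec <- list(...)
  as.data.frame(lapply(spec, function(type) {
    switch(type,
      integer = integer(0), numeric = numeric(0),
      character = character(0), logical = logical(0),
      stop("unknown column type ", type)
    )
  }), stringsAsFactors = FALSE)
}
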