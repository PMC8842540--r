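# Shared internal helpers: seeded RNG scopes, self-describing TSV i/o,
# classed error conditions.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state so seeded helpers do not perturb
#' the global stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      suppressWarnings(rm(".Random.seed", envir = env))
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a dataset-specific seed from a master seed
#'
#' One RNG stream per dataset keyed by (seed, name): keeps datasets
#' reproducible yet statistically independent of each other.
#'
#' @param seed Master integer seed.
#' @param name Character stream name.
#' @return An integer in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(name))
  h <- (as.double(seed) %% 2147483647) + 1
  for (ch in utf8ToInt(name)) h <- (h * 48271 + ch) %% 2147483647
  as.integer(h %% 2147483646 + 1)
}

# Cheap deterministic hash of an R object (config fingerprinting in file
# headers; not cryptographic).
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Classed condition helpers -------------------------------------------------

stop_rdnaepi <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "rdnaepi_error"), call = call))
}

undefined_correlation <- function(msg = "correlation undefined: constant input") {
  stop_rdnaepi(msg, "undefined_correlation")
}

# TSV with "# key: value" header lines --------------------------------------

#' Write a table as TSV with a self-describing comment header
#'
#' @param df A data.frame.
#' @param path Output file path.
#' @param meta Named list written as `# key: value` header lines.
#' @return `path`, invisibly.
#' @export
write_tsv_h <- function(df, path, meta = list()) {
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  if (length(meta)) {
    hdr <- sprintf("# %s: %s", names(meta), vapply(meta, function(v)
      paste(format(v, trim = TRUE), collapse = ","), character(1)))
    writeLines(hdr, con, sep = "\n", useBytes = TRUE)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read a TSV written by [write_tsv_h()]
#'
#' @param path File path.
#' @return A data.frame; header metadata in attribute `"meta"`.
#' @export
read_tsv_h <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  if (length(hdr)) {
    kv <- sub("^#\\s*", "", lines[hdr])
    keys <- sub(":.*$", "", kv)
    vals <- sub("^[^:]*:\\s*", "", kv)
    meta <- stats::setNames(as.list(vals), keys)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  attr(df, "meta") <- meta
  df
}

# Binary (Shannon) entropy in bits, 0*log0 == 0.
binary_entropy <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  term <- function(q) ifelse(q <= 0 | q >= 1, 0, -q * log2(q))
  term(p) + term(1 - p)
}
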