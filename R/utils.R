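#' Evaluate an expression with a local random seed
#'
#' Runs `code` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards so package functions never leak randomness into the
#' user's session.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Derive a child seed from a parent seed; keeps every stream traceable to
# the single study seed while avoiding overlapping draws between stages.
child_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483629)
}

#' Hash text content
#'
#' Polynomial rolling hash (base 131, modulus 2^31 - 1) over the UTF-8
#' bytes of `x`, used for provenance entries in run manifests. Not
#' cryptographic; only identity of text artifacts matters here.
#'
#' @param x Character vector (collapsed with newlines) or path of an
#'   existing file whose lines are hashed.
#' @return Hexadecimal hash string.
#' @export
content_hash <- function(x) {
  if (length(x) == 1L && file.exists(x)) x <- readLines(x, warn = FALSE)
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  p <- 2147483647
  h <- 0
  block <- 512L
  pow <- numeric(block)
  pow[block] <- 1
  for (j in rev(seq_len(block - 1L))) pow[j] <- (pow[j + 1L] * 131) %% p
  powk <- (pow[1L] * 131) %% p # 131^block mod p
  n <- length(bytes)
  i <- 1L
  while (i <= n) {
    j <- min(i + block - 1L, n)
    chunk <- bytes[i:j]
    k <- length(chunk)
    ph <- if (k == block) pow else pow[(block - k + 1L):block]
    bh <- sum((chunk * ph) %% p) %% p
    mult <- if (k == block) powk else ((pow[block - k] * 131) %% p)
    h <- (h * mult + bh) %% p
    i <- j + 1L
  }
  sprintf("%08x", h)
}

# Internal logger: silent unless options(geoGCF.verbose = TRUE).
gcf_log <- function(...) {
  if (isTRUE(getOption("geoGCF.verbose", FALSE))) {
    message("[geoGCF] ", ...)
  }
  invisible(NULL)
}

# Locale-independent (C-collation) sort/order so every artifact is
# byte-identical regardless of the session's LC_COLLATE.
c_sort <- function(x) sort(x, method = "radix")
c_order <- function(...) order(..., method = "radix")

# stopifnot-style check with a formatted message
check_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}
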