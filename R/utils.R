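#' @keywords internal
"_PACKAGE"

# package-level cache for bundled tables
.doxpbpk_env <- new.env(parent = emptyenv())

`%||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Convert a dose in mg to nmol
#'
#' @param mg dose in milligrams.
#' @param molecular_weight molecular weight in g/mol.
#' @return dose in nmol.
#' @examples
#' mg_to_nmol(75, 279.37)
#' @export
mg_to_nmol <- function(mg, molecular_weight) {
  stopifnot(is.numeric(mg), is.numeric(molecular_weight),
            molecular_weight > 0)
  mg * 1e6 / molecular_weight
}

# mg/L -> nmol/L
mg_per_L_to_nmol_per_L <- function(mg_L, molecular_weight) {
  mg_L * 1e6 / molecular_weight
}

#' Round half up to a number of decimal places
#'
#' Display rounding used for fold-error reporting (the usual IEEE
#' round-half-even of [round()] would print 2.545 as 2.54).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `code` with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG state afterwards so library code never disturbs user RNG.
with_seed <- function(seed, code) {
  seed <- as.integer(seed %% .Machine$integer.max)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Tiny FNV-1a hash of a character scalar, for tagging outputs with a
# reproducible configuration fingerprint without external dependencies.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # XOR with a byte only touches the low 8 bits; keeps h a double
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    # 32-bit multiply by the FNV prime, split to stay within exact doubles
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  # render as hex from the two 16-bit halves (h is a double)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "doxpbpk")
  if (!nzchar(path)) {
    stop("bundled data file not found: ", file, call. = FALSE)
  }
  path
}

read_bundled_csv <- function(file) {
  utils::read.csv(extdata_path(file), comment.char = "#",
                  stringsAsFactors = FALSE)
}
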