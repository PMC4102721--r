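# internal helpers shared across modules

BASES <- c("A", "C", "G", "T")

# IUPAC code for an unordered base pair (used for heterozygous amplicon reads)
IUPAC2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

iupac_pair <- function(b1, b2) {
  key <- paste0(sort(c(b1, b2)), collapse = "")
  unname(IUPAC2[key])
}

iupac_expand <- function(code) {
  hit <- names(IUPAC2)[match(code, IUPAC2)]
  if (is.na(hit)) return(NULL)
  c(substr(hit, 1, 1), substr(hit, 2, 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed for one operation
#'
#' All stochastic operations draw their seed from a single master seed plus a
#' short operation label, so any stage of a simulation can be replayed in
#' isolation without re-running the stages before it.
#'
#' @param seed master integer seed.
#' @param op character label of the operation.
#' @return an integer seed below 2^31.
#' @export
substream <- function(seed, op) {
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op)))
  as.integer((as.numeric(seed) * 48271 + h * 2654435) %% 2147483629L)
}

# round half away from zero, matching how the printed percentages were rounded
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x == floor(x)
}

is_prob <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

next_prime <- function(n) {
  n <- max(2L, as.integer(ceiling(n)))
  is_prime <- function(k) {
    if (k < 4) return(k >= 2)
    if (k %% 2 == 0) return(FALSE)
    d <- 3
    while (d * d <= k) {
      if (k %% d == 0) return(FALSE)
      d <- d + 2
    }
    TRUE
  }
  while (!is_prime(n)) n <- n + 1L
  n
}

# integer base vector -> character sequence and back
bases_to_string <- function(x) paste(BASES[x], collapse = "")

string_to_bases <- function(s) {
  v <- match(strsplit(toupper(s), "")[[1]], BASES)
  v
}
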