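# Internal numerical helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Swish activation
#'
#' `swish(x) = x * sigmoid(x)`, the smooth non-linearity used throughout the
#' encoder (edge embedding, convolution filter, update and output MLPs).
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape as `x`.
#' @export
swish <- function(x) x * sigmoid(x)

# d/dx swish(x), expressed in terms of the pre-activation x
swish_grad <- function(x) {
  s <- sigmoid(x)
  s * (1 + x * (1 - s))
}

# add a row vector b to every row of matrix M without forming t(t(M) + b)
add_bias <- function(M, b) M + rep(b, each = nrow(M))

# sum rows of `M` into `n` groups given by integer `index` (1..n); rows of the
# result are ordered 1..n and groups with no members are zero.
scatter_sum <- function(M, index, n) {
  if (is.null(dim(M))) M <- matrix(M, ncol = 1L)
  out <- rowsum(rbind(M, matrix(0, n, ncol(M))), c(index, seq_len(n)))
  dimnames(out) <- NULL
  out
}

# run `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

# element symbol -> atomic number lookup (H..Lr)
.ELEMENTS <- c(
  "H", "HE", "LI", "BE", "B", "C", "N", "O", "F", "NE",
  "NA", "MG", "AL", "SI", "P", "S", "CL", "AR", "K", "CA",
  "SC", "TI", "V", "CR", "MN", "FE", "CO", "NI", "CU", "ZN",
  "GA", "GE", "AS", "SE", "BR", "KR", "RB", "SR", "Y", "ZR",
  "NB", "MO", "TC", "RU", "RH", "PD", "AG", "CD", "IN", "SN",
  "SB", "TE", "I", "XE", "CS", "BA", "LA", "CE", "PR", "ND",
  "PM", "SM", "EU", "GD", "TB", "DY", "HO", "ER", "TM", "YB",
  "LU", "HF", "TA", "W", "RE", "OS", "IR", "PT", "AU", "HG",
  "TL", "PB", "BI", "PO", "AT", "RN", "FR", "RA", "AC", "TH",
  "PA", "U", "NP", "PU", "AM", "CM", "BK", "CF", "ES", "FM",
  "MD", "NO", "LR"
)

element_to_z <- function(symbol, context = "atom record") {
  z <- match(toupper(trimws(symbol)), .ELEMENTS)
  if (anyNA(z)) {
    bad <- unique(symbol[is.na(z)])
    stop(sprintf("unknown element symbol(s) in %s: %s", context,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  as.integer(z)
}
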