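# Internal helpers shared across modules.

# log(sum(exp(x))) guarded against -Inf everywhere
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Natural chromosome ordering: 1..22 numerically, then X, Y, then anything
# else alphabetically. String sort would put "10" before "2".
chrom_order <- function(chroms) {
  u <- unique(as.character(chroms))
  num <- suppressWarnings(as.numeric(u))
  is_num <- !is.na(num)
  special <- c("X", "Y")
  rest <- setdiff(u[!is_num], special)
  c(u[is_num][order(num[is_num])], special[special %in% u], sort(rest))
}

# Deterministic 32-bit sub-seed from a master seed and a label, so each
# stage/replicate gets its own reproducible stream.
derive_seed <- function(master, label) {
  h <- as.double(master) %% 2147483647
  for (b in utf8ToInt(paste0("#", label))) {
    h <- (h * 131 + b) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_load <- function(...) stop(sprintf(...), call. = FALSE)
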