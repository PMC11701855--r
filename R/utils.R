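# Internal helpers shared across modules.

# Contract-style assertion: user-facing argument errors.
check_that <- function(ok, msg, class = "decorrens_contract_error") {
  if (!isTRUE(ok)) rlang::abort(msg, class = class)
  invisible(TRUE)
}

# Domain errors (invalid scientific parameter values).
check_domain <- function(ok, msg) {
  check_that(ok, msg, class = "decorrens_domain_error")
}

is_count <- function(x, positive = TRUE) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) &&
    (!positive || x >= 1)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Deterministic derived seeds: keeps every sub-stream a pure function of the
# run seed while staying inside 32-bit integer range.
derive_seed <- function(seed, k) {
  v <- ((as.numeric(seed) %% 2147483647) * 7919 + 104729 * as.numeric(k))
  as.integer(v %% 2147483647)
}

# Numerically stable log-sum-exp over matrix rows.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

row_softmax <- function(m) {
  mx <- apply(m, 1L, max)
  e <- exp(m - mx)
  e / rowSums(e)
}

# x * log(x) with the 0 * log(0) := 0 convention.
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

# Trapezoidal integral of y over x.
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
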