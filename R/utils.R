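# internal helpers ----------------------------------------------------------

# approximate relative physical lengths of the 22 human autosomes (Mb)
autosome_mb <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
                 115, 107, 102, 90, 81, 78, 59, 63, 48, 51)

stop_arg <- function(msg) abort(msg, class = "cnvconcord_argument_error")
stop_structural <- function(msg) abort(msg, class = "cnvconcord_structural_error")
stop_undefined <- function(msg) abort(msg, class = "cnvconcord_undefined")

check_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != round(x))
    stop_arg(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
    stop_arg(sprintf("`%s` must be a single value in [0, 1]", name))
  as.numeric(x)
}

# split n into `length(weights)` integer counts proportional to weights,
# assigning remainders by largest fractional part (deterministic)
proportional_counts <- function(n, weights) {
  w <- weights / sum(weights)
  raw <- n * w
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# deterministic per-stage sub-seed derived from one master seed
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 131 + stage) %% 2147483629)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
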