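# internal helpers: argument checks and seed plumbing

stop_invalid <- function(...) {
  stop(structure(class = c("triomr_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_identification <- function(...) {
  stop(structure(class = c("triomr_identification_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop_invalid(name, " must be a single integer >= ", min, " (got ",
                 deparse(substitute(x)), " = ", format(x), ")")
  as.integer(x)
}

check_prob <- function(x, name, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
  if (!ok)
    stop_invalid(name, " must be a number in ",
                 if (open_lo) "(" else "[", lo, ", ", hi,
                 if (open_hi) ")" else "]")
  as.numeric(x)
}

# Derive a per-replicate (or per-stage) seed from a master seed and a counter,
# staying inside the 32-bit integer range. Deterministic and collision-free
# for counters up to ~2e9 / 40003.
derive_seed <- function(master, counter) {
  as.integer((as.double(master) + 40003 * as.double(counter)) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}
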