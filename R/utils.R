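# internal helpers shared across modules

geometric_mean <- function(x) exp(mean(log(x)))

# rescale positive divisors to geometric mean exactly 1
rescale_geomean <- function(x) x / geometric_mean(x)

# 75th percentile with linear interpolation on the sorted values
# (stats::quantile type 7); the dialect is fixed so results are reproducible
upper_quartile <- function(x) unname(stats::quantile(x, probs = 0.75, type = 7))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
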