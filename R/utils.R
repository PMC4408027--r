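# Internal helpers shared across modules.

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generation never disturbs user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

check_positive <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop("`", name, "` must be positive and finite", call. = FALSE)
  }
  invisible(x)
}

# mean/sd in natural units -> lognormal meanlog/sdlog by moment matching
lognormal_pars <- function(mean, sd) {
  mean <- unname(mean); sd <- unname(sd)
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log1p(cv2))
  c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# rejection-sample a lognormal truncated to [lo, hi]
rtrunc_lnorm <- function(n, mean, sd, lo = 0, hi = Inf) {
  p <- lognormal_pars(mean, sd)
  out <- numeric(0)
  guard <- 0L
  while (length(out) < n) {
    x <- stats::rlnorm(n * 4L, p["meanlog"], p["sdlog"])
    out <- c(out, x[x >= lo & x <= hi])
    guard <- guard + 1L
    if (guard > 100L) {
      stop("truncated lognormal sampler failed: bounds [", lo, ", ", hi,
           "] too tight for mean ", mean, call. = FALSE)
    }
  }
  out[seq_len(n)]
}
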