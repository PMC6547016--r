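# Shared internal helpers.

# Timestamps are timezone-naive local clock times; internally they are stored
# as POSIXct pinned to UTC so arithmetic is unambiguous and serialisation is
# a plain ISO-8601 string with no zone suffix.
parse_naive_datetime <- function(x) {
  if (inherits(x, "POSIXct")) {
    return(as.POSIXct(format(x, "%Y-%m-%d %H:%M:%S", tz = attr(x, "tzone") %||% ""),
                      tz = "UTC"))
  }
  x <- as.character(x)
  out <- rep(NA_real_, length(x))
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  for (f in fmts) {
    need <- is.na(out) & !is.na(x)
    if (!any(need)) break
    out[need] <- as.numeric(strptime(x[need], f, tz = "UTC"))
  }
  .POSIXct(out, tz = "UTC")
}

format_naive_datetime <- function(x) {
  ifelse(is.na(x), NA_character_, format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

hours_between <- function(later, earlier) {
  as.numeric(difftime(later, earlier, units = "hours"))
}

# Draw from a normal truncated to [lo, hi] by inverse-CDF sampling.
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream. With seed = NULL the global stream is used (and advanced).
with_preserved_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

stop_input <- function(msg, class = "newsfio2_input_error") {
  abort(msg, class = class)
}

stop_domain <- function(msg) {
  abort(msg, class = "newsfio2_domain_error")
}
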