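# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state on exit.
with_preserved_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Coerce a two-level grouping into a factor; `event_level`, if given, is
# placed second so that it codes the event (atherosclerotic) class.
as_two_groups <- function(labels, event_level = NULL) {
  g <- factor(labels)
  if (nlevels(g) != 2L)
    stop("exactly two groups are required, got ", nlevels(g), call. = FALSE)
  if (!is.null(event_level)) {
    if (!event_level %in% levels(g))
      stop("event level '", event_level, "' not present in labels", call. = FALSE)
    g <- factor(g, levels = c(setdiff(levels(g), event_level), event_level))
  }
  g
}

# Vectorised two-sided equal-variance t-test over the rows of `x`.
# Returns per-row group means, SDs, pooled t and p.
row_t_test <- function(x, g) {
  g <- as_two_groups(g)
  i1 <- g == levels(g)[1L]
  i2 <- g == levels(g)[2L]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 samples", call. = FALSE)
  x1 <- x[, i1, drop = FALSE]
  x2 <- x[, i2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- (m2 - m1) / se
  tt[se == 0 & m1 == m2] <- 0
  df <- n1 + n2 - 2
  list(mean1 = m1, mean2 = m2, sd1 = sqrt(v1), sd2 = sqrt(v2),
       t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

# Binary event indicator (1 = event) from labels; second factor level is the
# event unless `event_level` names it.
event_indicator <- function(labels, event_level = NULL) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (!all(u %in% c(0, 1))) stop("numeric labels must be 0/1", call. = FALSE)
    return(as.integer(labels))
  }
  g <- as_two_groups(labels, event_level)
  as.integer(g == levels(g)[2L])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
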