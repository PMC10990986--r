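# Textbook Pearson correlation with a two-sided p from the t transform:
# the independent oracle the correlation machinery is checked against.
pearson_manual <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# Hand-built three-narrative annotated corpus with known per-sentence
# structure; used by io/prep/scoring unit tests.
tiny_annotations <- function() {
  narratives <- tibble::tibble(
    narrative_id = c("n1", "n2", "n3"),
    dataset_id = c("dsA", "dsA", "dsB"),
    task = c("memory", "memory", "future"),
    text = c(
      "we sat on the warm sand. I always love beaches.",
      "aa bb cc dd ee. ff gg hh.",
      "one two three four."
    )
  )
  segments <- tibble::tibble(
    narrative_id = c("n1", "n1", "n2", "n2", "n3"),
    segment_index = c(0L, 1L, 0L, 1L, 0L),
    text = c(
      "we sat on the warm sand.", "I always love beaches.",
      "aa bb cc dd ee.", "ff gg hh.",
      "one two three four."
    ),
    category = c("internal", "external", "internal", "external", "internal"),
    detail_count = c(3L, 1L, 2L, 1L, 2L)
  )
  annotated_corpus(narratives, segments)
}

quadrant_r <- function(report, quadrant) {
  report$r[report$quadrant == quadrant]
}

# brute-force nearest-center binning with higher-class tie-break
bin_fraction_bruteforce <- function(fraction) {
  centers <- c(P0 = 0, P50 = 0.5, P75 = 0.75, P100 = 1)
  vapply(fraction, function(f) {
    d <- abs(f - centers)
    names(centers)[max(which(d == min(d)))]
  }, character(1))
}
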