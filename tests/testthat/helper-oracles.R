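# Independent oracles, coded from first principles and kept separate from
# the implementation paths they check.

# Welch test from the textbook formulas, scalar arithmetic only.
welchOracle <- function(x, y) {
    v1 <- sum((x - mean(x))^2) / (length(x) - 1)
    v2 <- sum((y - mean(y))^2) / (length(y) - 1)
    se2 <- v1 / length(x) + v2 / length(y)
    tt <- (mean(y) - mean(x)) / sqrt(se2)
    df <- se2^2 / ((v1 / length(x))^2 / (length(x) - 1) +
                   (v2 / length(y))^2 / (length(y) - 1))
    2 * pt(-abs(tt), df)
}

# Exhaustive all-pairs AUC with half credit for ties.
aurocOracle <- function(normal, tumor) {
    wins <- 0
    for (t in tumor) for (n in normal)
        wins <- wins + (t > n) + 0.5 * (t == n)
    wins / (length(normal) * length(tumor))
}

# Benjamini-Hochberg step-up, hand-coded.
bhOracle <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
}

# Two-pass Pearson correlation.
corOracle <- function(x, y) {
    mx <- sum(x) / length(x); my <- sum(y) / length(y)
    sum((x - mx) * (y - my)) /
        sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
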