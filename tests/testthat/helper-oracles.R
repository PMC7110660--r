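# Independent brute-force oracle for the two-sided Mann-Whitney U test:
# enumerate every placement of the gene sample's ranks among the pooled
# ranks and accumulate both tail probabilities of U.
mw_enum_p <- function(x, y) {
    n <- length(x)
    r <- rank(c(x, y))
    u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    us <- mw_enum_null_u(n, length(y))
    min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# all possible U values under the null (uniform over rank placements)
mw_enum_null_u <- function(n, m) {
    combs <- utils::combn(n + m, n)
    colSums(combs) - n * (n + 1) / 2
}

# data realizing a given rank placement of the gene sample among n + m
# distinct values
mw_data_for_placement <- function(placement, n_total) {
    vals <- seq_len(n_total) / 7  # arbitrary distinct, no ties
    list(x = vals[placement], y = vals[-placement])
}
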