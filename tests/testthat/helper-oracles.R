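# Independent brute-force oracles used across the suite. They deliberately
# share no code with the implementation paths they check.

# exhaustive largest-overlap assignment over all read x gene pairs
assignOracle <- function(reads, genes) {
    vapply(seq_along(reads), function(i) {
        ov <- vapply(seq_along(genes), function(j) {
            if (as.character(seqnames(reads)[i]) !=
                as.character(seqnames(genes)[j])) return(0L)
            if (as.character(strand(reads)[i]) !=
                as.character(strand(genes)[j])) return(0L)
            max(0L, min(end(reads)[i], end(genes)[j]) -
                    max(start(reads)[i], start(genes)[j]) + 1L)
        }, integer(1))
        if (all(ov == 0L)) return("Unassigned_NoFeature")
        best <- which(ov == max(ov))
        if (length(best) > 1L) return("Unassigned_Ambiguity")
        genes$gene_id[best]
    }, character(1))
}

# O(n^2) transitive closure (BFS over the <= maxGap adjacency graph)
clusterOracle <- function(positions, maxGap) {
    u <- sort(unique(positions))
    n <- length(u)
    if (n == 0L) return(list())
    comp <- integer(n)
    k <- 0L
    for (i in seq_len(n)) {
        if (comp[i] != 0L) next
        k <- k + 1L
        queue <- i
        comp[i] <- k
        while (length(queue)) {
            cur <- queue[1L]
            queue <- queue[-1L]
            nb <- which(comp == 0L & abs(u - u[cur]) <= maxGap)
            comp[nb] <- k
            queue <- c(queue, nb)
        }
    }
    unname(split(u, comp))
}

# exact two-sided permutation p-value of the Mann-Whitney U statistic
permRankSumP <- function(x, y) {
    all <- c(x, y)
    n <- length(x)
    r <- rank(all)
    combs <- utils::combn(length(all), n)
    U <- colSums(matrix(r[combs], nrow = n)) - n * (n + 1) / 2
    u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    min(1, 2 * min(mean(U <= u), mean(U >= u)))
}

# sort-and-index median
medianOracle <- function(x) {
    s <- sort(x)
    n <- length(s)
    if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}
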