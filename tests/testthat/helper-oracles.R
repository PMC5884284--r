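# Independent reference implementations used as oracles. These are kept
# deliberately naive (plain loops, no shared code with the package
# internals beyond exported montage constructors).

m8 <- standard_montage("10-10-8ch")
m19 <- standard_montage("10-20-19ch")

# Greedy fuzzy growth, pure R
oracle_fuzzy <- function(phases, r) {
  n <- length(phases)
  out <- list()
  for (seed in seq_len(n)) {
    members <- seed
    repeat {
      rest <- setdiff(seq_len(n), members)
      if (length(rest) == 0L) break
      rb <- sapply(rest, function(m) {
        ang <- phases[c(members, m)]
        sqrt(mean(cos(ang))^2 + mean(sin(ang))^2)
      })
      if (max(rb) < r) break
      members <- c(members, rest[which.max(rb)])
    }
    out[[seed]] <- sort(members)
  }
  keys <- sapply(out, paste, collapse = ",")
  out[!duplicated(keys)]
}

oracle_rbar <- function(ang) sqrt(mean(cos(ang))^2 + mean(sin(ang))^2)

# Hard conversion, pure R, mirroring the documented contract
oracle_hard <- function(fuzzy_members, phases, r) {
  n <- length(phases)
  total_bits <- 4 * ceiling(n / 4)
  cand <- fuzzy_members
  taken <- integer(0)
  clusters <- list()
  repeat {
    pool <- list()
    for (m in cand) {
      red <- setdiff(m, taken)
      if (length(red) == 0L) next
      if (any(sapply(pool, identical, red))) next
      rb <- oracle_rbar(phases[red])
      if (length(red) > 1L && rb < r) next
      pool[[length(pool) + 1L]] <- red
    }
    if (length(pool) == 0L) break
    rb <- sapply(pool, function(m) oracle_rbar(phases[m]))
    sz <- lengths(pool)
    code <- sapply(pool, function(m) sum(2^(total_bits - m)))
    best <- order(-rb, -sz, code)[1]
    clusters[[length(clusters) + 1L]] <- pool[[best]]
    taken <- c(taken, pool[[best]])
    cand <- pool
    if (length(taken) == n) break
  }
  for (j in setdiff(seq_len(n), taken)) clusters[[length(clusters) + 1L]] <- j
  clusters
}

# All set partitions of 1..n (restricted growth strings)
oracle_partitions <- function(n) {
  out <- list()
  rec <- function(assign, next_block) {
    i <- length(assign) + 1L
    if (i > n) {
      blocks <- split(seq_len(n), assign)
      out[[length(out) + 1L]] <<- unname(blocks)
      return(invisible())
    }
    for (b in seq_len(next_block)) {
      rec(c(assign, b), max(next_block, b + 1L))
    }
  }
  rec(integer(0), 1L)
  out
}

# Hamming distance between equal-length bit strings, via character compare
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

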