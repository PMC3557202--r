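# Brute-force oracle: the exact distribution over trajectories, obtained by
# enumerating every initial state (weighted by the spread distribution) and
# every sequence of update orders (uniform over permutations at each step).
# Written directly from the declared transition semantics in plain R,
# independent of the package's compiled engine.

oracle_update <- function(cur, infl) {
  if (infl > 0) return(min(cur + 1L, 2L))
  if (infl < 0) return(max(cur - 1L, 0L))
  if (cur > 1L) return(cur - 1L)
  if (cur < 1L) return(cur + 1L)
  1L
}

# hist: matrix with rows 1..i = states at steps 0..i-1; returns state after
# one pass in the given order
oracle_pass <- function(net, hist, ord) {
  nd <- net$nodes
  ed <- net$edges
  i <- nrow(hist)
  w <- hist[i, ]
  for (v in ord) {
    inc <- ed[ed$target == v, , drop = FALSE]
    infl <- 0L
    for (j in seq_len(nrow(inc))) {
      d <- inc$delay[j]
      st <- if (d == 0L) w[[inc$source[j]]]
            else if (i - d >= 1L) hist[i - d, inc$source[j]]
            else 1L
      infl <- infl + (if (inc$sign[j] == "activate") 1L else -1L) * (st - 1L)
    }
    w[[v]] <- oracle_update(w[[v]], infl)
  }
  fixed <- nd$role != "ordinary"
  w[nd$name[fixed]] <- nd$clamp_level[fixed]
  w
}

# returns named numeric vector: P(trajectory), keyed by the concatenated
# row-wise state string (step 0 first, nodes in net$nodes order)
oracle_distribution <- function(net, horizon, p) {
  nd <- net$nodes
  ordinary <- nd$name[nd$role == "ordinary"]
  k <- length(ordinary)
  perms <- all_perms(ordinary)
  pperm <- 1 / length(perms)

  inits <- list(list(prob = 1, s = integer(0)))
  for (v in ordinary) {
    inits <- do.call(c, lapply(inits, function(br) {
      lapply(1:3, function(j) {
        st <- c(0L, 1L, 2L)[j]
        pr <- c(p, 1 - 2 * p, p)[j]
        list(prob = br$prob * pr, s = c(br$s, st))
      })
    }))
  }
  inits <- Filter(function(b) b$prob > 0, inits)

  acc <- new.env(parent = emptyenv())
  fixed <- nd$role != "ordinary"
  recurse <- function(hist, prob, steps_left) {
    if (steps_left == 0L) {
      key <- paste(as.vector(t(hist)), collapse = "")
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + prob
      return(invisible())
    }
    for (ord in perms) {
      nxt <- oracle_pass(net, hist, ord)
      recurse(rbind(hist, nxt), prob * pperm, steps_left - 1L)
    }
  }
  for (br in inits) {
    s0 <- integer(nrow(nd))
    names(s0) <- nd$name
    s0[fixed] <- nd$clamp_level[fixed]
    s0[ordinary] <- br$s
    recurse(matrix(s0, nrow = 1, dimnames = list(NULL, nd$name)),
            br$prob, horizon)
  }
  unlist(as.list(acc))
}

# exact expected mean trajectory from the oracle distribution
oracle_mean <- function(dist, n_nodes, horizon) {
  keys <- names(dist)
  m <- matrix(0, horizon + 1L, n_nodes)
  for (i in seq_along(keys)) {
    states <- as.integer(strsplit(keys[i], "")[[1]])
    m <- m + dist[i] * matrix(states, horizon + 1L, n_nodes, byrow = TRUE)
  }
  m
}

# trajectory keys for an ensemble run with keep_runs = TRUE
ensemble_keys <- function(ens) {
  apply(ens$runs, 3, function(tr) paste(as.vector(t(tr)), collapse = ""))
}

# chi-square goodness of fit of observed trajectory keys against the oracle
# distribution, merging low-expectation bins
oracle_chisq_p <- function(keys, dist, min_exp = 5) {
  n <- length(keys)
  obs <- table(factor(keys, levels = names(dist)))
  stopifnot(sum(obs) == n)  # every observed trajectory must be enumerable
  exp_cnt <- dist * n
  o <- order(exp_cnt)
  obs <- as.numeric(obs)[o]
  exp_cnt <- exp_cnt[o]
  grp <- integer(length(exp_cnt))
  g <- 1L
  run <- 0
  for (i in seq_along(exp_cnt)) {
    grp[i] <- g
    run <- run + exp_cnt[i]
    if (run >= min_exp) { g <- g + 1L; run <- 0 }
  }
  if (run > 0 && g > 1L) grp[grp == g] <- g - 1L
  O <- tapply(obs, grp, sum)
  E <- tapply(exp_cnt, grp, sum)
  if (length(O) < 2L) return(1)
  stat <- sum((O - E)^2 / E)
  stats::pchisq(stat, df = length(O) - 1L, lower.tail = FALSE)
}
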