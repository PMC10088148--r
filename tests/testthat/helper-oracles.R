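## Independent oracles used across the suite. These are deliberately naive
## (explicit formulas, O(n^2) enumeration, grid/golden-section maximisation)
## and share no code with the package internals they check.

## Efron partial log-likelihood for a single binary covariate ---------------
efronPartialLoglik <- function(beta, x, time, event) {
  eta <- beta * x
  w <- exp(eta)
  ll <- 0
  for (t0 in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t0)
    R <- which(time >= t0)
    d <- length(D)
    sumD <- sum(w[D])
    sumR <- sum(w[R])
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1L) {
      ll <- ll - log(sumR - (l / d) * sumD)
    }
  }
  ll
}

## brute-force maximiser of the Efron partial likelihood: staged grid
## refinement down to ~1e-6 spacing (below that the likelihood is flat to
## machine noise), then one parabolic vertex through the best three grid
## points, good to ~1e-9
efronOracleBeta <- function(x, time, event, lower = -8, upper = 8) {
  lo <- lower; hi <- upper
  repeat {
    grid <- seq(lo, hi, length.out = 401L)
    step <- grid[2] - grid[1]
    ll <- vapply(grid, function(b) efronPartialLoglik(b, x, time, event),
                 numeric(1))
    k <- which.max(ll)
    best <- grid[k]
    if (step <= 1e-6) {
      if (k > 1 && k < length(grid)) {
        denom <- ll[k - 1] - 2 * ll[k] + ll[k + 1]
        if (denom < 0) {
          best <- best + step / 2 * (ll[k - 1] - ll[k + 1]) / denom
        }
      }
      return(best)
    }
    span <- 10 * step
    lo <- best - span; hi <- best + span
  }
}

## Harrell concordance by exhaustive pair enumeration -----------------------
## Pair semantics (matching the usable-pair definition): with t_i < t_j the
## pair is usable iff subject i had the event; equal times are usable only
## when exactly one of the two is an event (the event precedes the censored
## survivor); both-event ties are not usable. Risk ties count 1/2.
cindexOracle <- function(risk, time, event) {
  n <- length(risk)
  conc <- disc <- tied <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- i; b <- j
      if (time[b] < time[a] ||
          (time[b] == time[a] && event[b] == 1 && event[a] == 0)) {
        a <- j; b <- i
      }
      if (time[a] == time[b] && event[a] == 1 && event[b] == 1) next
      if (event[a] != 1) next
      if (risk[a] > risk[b]) conc <- conc + 1
      else if (risk[a] == risk[b]) tied <- tied + 1
      else disc <- disc + 1
    }
  }
  den <- conc + disc + tied
  list(c = if (den == 0) NA_real_ else (conc + tied / 2) / den,
       concordant = conc, discordant = disc, tiedRisk = tied)
}

## small synthetic survival data set ----------------------------------------
makeSurvData <- function(n, rate = 0.05, censRate = 0.02, lp = 0,
                         admin = 120) {
  t <- rexp(n, rate * exp(lp))
  c0 <- pmin(rexp(n, censRate), admin)
  list(time = pmin(t, c0), event = as.integer(t <= c0))
}

## pure-signature subgroup block matrix (recurrent drivers + del5q) ---------
makeSignatureBlocks <- function(n, labelNoise = 0.05, seed = 1) {
  set.seed(seed)
  truth <- sample(1:4, n, replace = TRUE)
  planted <- truth
  flip <- runif(n) < labelNoise
  planted[flip] <- sample(1:4, sum(flip), replace = TRUE)
  sig <- list(c("DNMT3A", "STAG2", "ASXL1"), "TET2", "RUNX1",
              c("TP53", "del5q"))
  feats <- c("DNMT3A", "STAG2", "ASXL1", "TET2", "RUNX1", "TP53", "del5q")
  m <- matrix(0L, n, length(feats),
              dimnames = list(sprintf("P%04d", seq_len(n)), feats))
  for (i in seq_len(n)) m[i, sig[[planted[i]]]] <- 1L
  list(matrix = m, planted = planted, intended = truth)
}
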