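# Brute-force reference implementations, written independently of the
# package internals (explicit loops, no shared helpers). Used to check
# the closed-form classifiers by oracle equivalence.

bruteLDAPredict <- function(xtr, ytr, xte, lambda = 1e-6) {
  classes <- sort(unique(ytr))
  p <- ncol(xtr)
  mus <- list(); priors <- numeric(length(classes))
  S <- matrix(0, p, p)
  for (k in seq_along(classes)) {
    rows <- which(ytr == classes[k])
    priors[k] <- length(rows) / nrow(xtr)
    mu <- numeric(p)
    for (j in seq_len(p)) mu[j] <- mean(xtr[rows, j])
    mus[[k]] <- mu
    for (i in rows) {
      d <- xtr[i, ] - mu
      S <- S + outer(d, d)
    }
  }
  S <- S / max(nrow(xtr) - length(classes), 1)
  S <- S + diag(lambda * sum(diag(S)) / p, p)
  out <- character(nrow(xte))
  for (i in seq_len(nrow(xte))) {
    best <- -Inf; lab <- NA_character_
    for (k in seq_along(classes)) {
      a <- solve(S, mus[[k]])
      delta <- sum(xte[i, ] * a) - 0.5 * sum(mus[[k]] * a) + log(priors[k])
      if (delta > best) { best <- delta; lab <- classes[k] }
    }
    out[i] <- lab
  }
  out
}

bruteNBCPredict <- function(xtr, ytr, xte) {
  classes <- sort(unique(ytr))
  p <- ncol(xtr)
  mus <- vars <- list(); priors <- numeric(length(classes))
  for (k in seq_along(classes)) {
    rows <- which(ytr == classes[k])
    priors[k] <- length(rows) / nrow(xtr)
    mu <- v <- numeric(p)
    for (j in seq_len(p)) {
      mu[j] <- mean(xtr[rows, j])
      v[j] <- mean((xtr[rows, j] - mu[j])^2)
    }
    mus[[k]] <- mu; vars[[k]] <- v
  }
  floorv <- 1e-9 * max(unlist(vars))
  out <- character(nrow(xte))
  for (i in seq_len(nrow(xte))) {
    best <- -Inf; lab <- NA_character_
    for (k in seq_along(classes)) {
      lp <- log(priors[k])
      for (j in seq_len(p))
        lp <- lp + dnorm(xte[i, j], mus[[k]][j],
                         sqrt(max(vars[[k]][j], floorv)), log = TRUE)
      if (lp > best) { best <- lp; lab <- classes[k] }
    }
    out[i] <- lab
  }
  out
}

bruteNN1Predict <- function(xtr, ytr, xte) {
  out <- character(nrow(xte))
  for (i in seq_len(nrow(xte))) {
    dmin <- Inf; lab <- NA_character_
    for (r in seq_len(nrow(xtr))) {
      d <- sqrt(sum((xte[i, ] - xtr[r, ])^2))
      if (d < dmin) { dmin <- d; lab <- ytr[r] }
    }
    out[i] <- lab
  }
  out
}

# AUC as the concordance fraction P(score+ > score-) + 0.5 P(tie), by
# exhaustive pair enumeration
bruteAUC <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}
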