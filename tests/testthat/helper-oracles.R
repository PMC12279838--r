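# Independent oracles, coded without reference to the package internals.

# FISTA (accelerated proximal gradient) for the standardized-scale LASSO
# objective (1/2n)||yc - Xs b||^2 + lambda ||b||_1. Returns the coefficient
# vector; with enough iterations the objective is accurate far below 1e-6
# on the small instances used in tests.
fistaLasso <- function(Xs, yc, lambda, iters = 20000L) {
    n <- nrow(Xs)
    L <- max(eigen(crossprod(Xs) / n, symmetric = TRUE,
                   only.values = TRUE)$values)
    step <- 1 / L
    b <- rep(0, ncol(Xs)); z <- b; tk <- 1
    soft <- function(u, l) sign(u) * pmax(abs(u) - l, 0)
    for (i in seq_len(iters)) {
        grad <- -crossprod(Xs, yc - Xs %*% z) / n
        bNew <- soft(z - step * grad, step * lambda)
        tNew <- (1 + sqrt(1 + 4 * tk^2)) / 2
        z <- bNew + (tk - 1) / tNew * (bNew - b)
        b <- bNew; tk <- tNew
    }
    b
}

# standardized-scale LASSO objective
lassoObjectiveStd <- function(Xs, yc, b, lambda) {
    n <- nrow(Xs)
    sum((yc - Xs %*% b)^2) / (2 * n) + lambda * sum(abs(b))
}

# population-sd standardization matching the model contract
standardizeCols <- function(X) {
    mu <- colMeans(X)
    Xc <- sweep(X, 2, mu)
    s <- sqrt(colMeans(Xc^2))
    list(Xs = sweep(Xc, 2, s, "/"), mu = mu, sd = s)
}

# original-scale LASSO objective with the penalty applied on the
# standardized coefficients (beta_std = beta_orig * sd)
lassoObjectiveOrig <- function(X, y, b0, beta, lambda, sds) {
    n <- length(y)
    sum((y - b0 - X %*% beta)^2) / (2 * n) + lambda * sum(sds * abs(beta))
}

# Independently coded moderated-t oracle: explicit per-feature loops and a
# bisection solver for the prior-df moment equation.
deaOracle <- function(v, isDiseased) {
    n1 <- sum(!isDiseased); n2 <- sum(isDiseased)
    dg <- n1 + n2 - 2
    G <- nrow(v)
    logfc <- s2 <- numeric(G)
    for (g in seq_len(G)) {
        a <- v[g, !isDiseased]; b <- v[g, isDiseased]
        logfc[g] <- mean(b) - mean(a)
        s2[g] <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / dg
    }
    e <- log(s2) - digamma(dg / 2) + log(dg / 2)
    rhs <- var(e) - trigamma(dg / 2)
    if (rhs <= 0) {
        d0 <- Inf
        s0sq <- exp(mean(e))
    } else {
        # bisection on log(y): trigamma decreasing, solve trigamma(y) = rhs
        lo <- log(1e-8); hi <- log(1e8)
        for (i in 1:200) {
            mid <- (lo + hi) / 2
            if (trigamma(exp(mid)) > rhs) lo <- mid else hi <- mid
        }
        d0 <- 2 * exp((lo + hi) / 2)
        s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
    st2 <- if (is.infinite(d0)) rep(s0sq, G) else
        (d0 * s0sq + dg * s2) / (d0 + dg)
    tt <- logfc / (sqrt(st2) * sqrt(1 / n1 + 1 / n2))
    p <- 2 * pt(-abs(tt), df = dg + d0)
    list(logfc = logfc, t = tt, p = p, d0 = d0, s0sq = s0sq)
}
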