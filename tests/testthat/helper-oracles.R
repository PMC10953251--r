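# Independent oracle implementations used to validate the estimators.
# These are written from the estimating-equation definitions using dense
# matrix algebra (solve of the normal equations), deliberately sharing no
# code with the package internals.

oracle_wls_origin <- function(bx, by, sey) {
  W <- diag(1 / sey^2, nrow = length(sey))
  X <- matrix(bx, ncol = 1)
  XtWX <- t(X) %*% W %*% X
  beta <- solve(XtWX, t(X) %*% W %*% by)
  res <- by - X %*% beta
  q <- as.numeric(t(res) %*% W %*% res)
  n <- length(bx)
  se_fixed <- sqrt(solve(XtWX)[1, 1])
  list(beta = as.numeric(beta), se_fixed = se_fixed, q = q,
       se_random = se_fixed * sqrt(max(1, q / (n - 1))))
}

oracle_egger <- function(bx, by, sey) {
  s <- ifelse(bx < 0, -1, 1)
  bx <- s * bx
  by <- s * by
  W <- diag(1 / sey^2, nrow = length(sey))
  X <- cbind(1, bx)
  XtWX <- t(X) %*% W %*% X
  beta <- solve(XtWX, t(X) %*% W %*% by)
  res <- by - X %*% beta
  n <- length(bx)
  sigma <- sqrt(as.numeric(t(res) %*% W %*% res) / (n - 2))
  se <- unname(sqrt(diag(solve(XtWX)))) * max(1, sigma)
  list(intercept = unname(beta[1]), slope = unname(beta[2]),
       intercept_se = se[1], slope_se = se[2])
}

oracle_mvmr <- function(X, y, sey) {
  W <- diag(1 / sey^2, nrow = length(sey))
  XtWX <- t(X) %*% W %*% X
  beta <- solve(XtWX, t(X) %*% W %*% y)
  res <- y - X %*% beta
  n <- nrow(X)
  p <- ncol(X)
  sigma2 <- as.numeric(t(res) %*% W %*% res) / (n - p)
  se <- unname(sqrt(diag(solve(XtWX)))) * sqrt(max(1, sigma2))
  list(beta = as.numeric(beta), se = se)
}

# Weighted 50% quantile by explicit search over the cumulative-weight
# step function with w/2 offsets.
oracle_weighted_median <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  cum <- numeric(length(w))
  run <- 0
  for (i in seq_along(w)) {
    cum[i] <- run + w[i] / 2
    run <- run + w[i]
  }
  if (cum[1] >= 0.5) return(b[1])
  if (cum[length(b)] <= 0.5) return(b[length(b)])
  i <- max(which(cum < 0.5))
  b[i] + (b[i + 1] - b[i]) * (0.5 - cum[i]) / (cum[i + 1] - cum[i])
}

# Dense-grid kernel-density argmax with the same (definitional) bandwidth
# rule but an independent, much finer evaluation grid.
oracle_mode <- function(b, w, factor = 1, grid_n = 20001) {
  w <- w / sum(w)
  if (length(unique(b)) == 1) return(b[1])
  s <- sd(b)
  m <- mad(b)
  h <- factor * 0.9 * min(s, if (m > 0) m else s) * length(b)^(-1 / 5)
  grid <- seq(min(b) - h, max(b) + h, length.out = grid_n)
  dens <- numeric(grid_n)
  for (j in seq_along(b)) {
    dens <- dens + w[j] * dnorm(grid, mean = b[j], sd = h)
  }
  grid[which.max(dens)]
}

# Term-by-term Cochran Q on the ratio scale.
oracle_q_ivw <- function(bx, by, sey) {
  theta <- by / bx
  se <- sey / abs(bx)
  w <- 1 / se^2
  bhat <- oracle_wls_origin(bx, by, sey)$beta
  total <- 0
  for (j in seq_along(theta)) total <- total + w[j] * (theta[j] - bhat)^2
  total
}
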