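#' Per-variable missingness report
#'
#' Fraction of missing entries per column, flagging variables above a
#' tolerance (available-case analysis is typically considered safe when every
#' variable stays below ~5% missing and the MCAR assumption holds).
#'
#' @param data data frame or matrix.
#' @param threshold flag fraction (default 0.05).
#' @return tibble with \code{variable}, \code{n_missing}, \code{fraction},
#'   \code{flagged}.
#' @export
missing_rate_report <- function(data, threshold = 0.05) {
  data <- as.data.frame(data)
  if (nrow(data) == 0) stop("empty data", call. = FALSE)
  frac <- vapply(data, function(col) mean(is.na(col)), numeric(1))
  tibble::tibble(
    variable = names(frac),
    n_missing = vapply(data, function(col) sum(is.na(col)), integer(1)),
    fraction = unname(frac),
    flagged = unname(frac) > threshold
  )
}

#' Little's test of missing completely at random (MCAR)
#'
#' Treats the data as multivariate normal, estimates the grand mean and
#' covariance by EM over the incomplete data, and compares each missingness
#' pattern's observed-variable means against the EM estimates:
#' \deqn{d^2 = \sum_j n_j (\bar y_j - \hat\mu_j)^\top \hat\Sigma_j^{-1}
#'   (\bar y_j - \hat\mu_j)}
#' restricted to the variables observed in pattern j, referred to a
#' chi-squared distribution with \eqn{\sum_j p_j - p} degrees of freedom.
#' A small p-value is evidence against MCAR. Ordinal scores entered here are
#' treated as numeric — a documented approximation, standard for this test.
#'
#' @param data numeric matrix/data frame with \code{NA}s; rows with no
#'   observed value are dropped.
#' @param tol EM convergence tolerance on the max absolute parameter change.
#' @param max_iter EM iteration cap.
#' @return list \code{d2}, \code{df}, \code{p_value}, \code{n_patterns},
#'   \code{patterns} (tibble: pattern string, n), \code{mu}, \code{sigma},
#'   \code{converged}. With a single missingness pattern the test is
#'   undefined: \code{d2 = 0}, \code{df = 0}, \code{p_value = NA}.
#' @export
little_mcar_test <- function(data, tol = 1e-6, max_iter = 500L) {
  x <- as.matrix(as.data.frame(data))
  storage.mode(x) <- "double"
  if (ncol(x) < 2) stop("need at least 2 variables", call. = FALSE)
  x <- x[rowSums(!is.na(x)) > 0, , drop = FALSE]
  n <- nrow(x)
  p <- ncol(x)
  obs <- !is.na(x)
  pattern_key <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  patterns <- split(seq_len(n), pattern_key)
  pat_tbl <- tibble::tibble(
    pattern = names(patterns),
    n = lengths(patterns)
  )
  fit <- em_mvnorm(x, tol = tol, max_iter = max_iter)
  if (length(patterns) < 2) {
    return(list(d2 = 0, df = 0L, p_value = NA_real_, n_patterns = length(patterns),
                patterns = pat_tbl, mu = fit$mu, sigma = fit$sigma,
                converged = fit$converged))
  }
  d2 <- 0
  df <- 0L
  for (rows in patterns) {
    o <- which(obs[rows[1], ])
    ybar <- colMeans(x[rows, o, drop = FALSE])
    dev <- ybar - fit$mu[o]
    sig <- fit$sigma[o, o, drop = FALSE]
    quad <- tryCatch(
      drop(crossprod(dev, solve(sig, dev))),
      error = function(e) {
        warning("singular pattern covariance; using ridge fallback", call. = FALSE)
        drop(crossprod(dev, solve(sig + diag(1e-8 * mean(diag(sig)), nrow(sig)), dev)))
      }
    )
    d2 <- d2 + length(rows) * quad
    df <- df + length(o)
  }
  df <- df - p
  list(d2 = d2, df = df,
       p_value = if (df > 0) pchisq(d2, df, lower.tail = FALSE) else NA_real_,
       n_patterns = length(patterns), patterns = pat_tbl,
       mu = fit$mu, sigma = fit$sigma, converged = fit$converged)
}

# Maximum-likelihood mean/covariance of multivariate normal data with
# ignorable missingness, by EM. Each E-step accumulates the conditional first
# and second moments of the missing block given the observed block; the
# M-step is the closed-form Gaussian update (ML, denominator n). Convergence
# on the max absolute change of any parameter.
em_mvnorm <- function(x, tol = 1e-6, max_iter = 500L) {
  n <- nrow(x)
  p <- ncol(x)
  obs <- !is.na(x)
  mu <- colMeans(x, na.rm = TRUE)
  v <- apply(x, 2, stats::var, na.rm = TRUE)
  v[!is.finite(v) | v <= 0] <- 1
  sigma <- diag(v, p)
  pattern_key <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), pattern_key)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    sum_x <- numeric(p)
    sum_xx <- matrix(0, p, p)
    for (rows in groups) {
      o <- which(obs[rows[1], ])
      m <- which(!obs[rows[1], ])
      xo <- x[rows, o, drop = FALSE]
      if (length(m) == 0) {
        sum_x <- sum_x + colSums(xo)
        sum_xx <- sum_xx + crossprod(xo)
        next
      }
      soo_inv <- solve(sigma[o, o, drop = FALSE])
      smo <- sigma[m, o, drop = FALSE]
      beta <- smo %*% soo_inv
      # conditional mean of the missing block for every row in this pattern
      xm_hat <- matrix(mu[m], nrow(xo), length(m), byrow = TRUE) +
        sweep(xo, 2, mu[o]) %*% t(beta)
      cond_cov <- sigma[m, m, drop = FALSE] - beta %*% t(smo)
      full <- matrix(0, nrow(xo), p)
      full[, o] <- xo
      full[, m] <- xm_hat
      sum_x <- sum_x + colSums(full)
      cp <- crossprod(full)
      cp[m, m] <- cp[m, m] + nrow(xo) * cond_cov
      sum_xx <- sum_xx + cp
    }
    mu_new <- sum_x / n
    sigma_new <- sum_xx / n - tcrossprod(mu_new)
    sigma_new <- (sigma_new + t(sigma_new)) / 2
    delta <- max(abs(mu_new - mu), abs(sigma_new - sigma))
    mu <- mu_new
    sigma <- sigma_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(mu = mu, sigma = sigma, converged = converged, iterations = iter)
}
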