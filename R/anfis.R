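## First-order Takagi-Sugeno ANFIS with grid partition.
##
## Layer structure: triangular memberships -> rule firing strengths
## (product t-norm) -> normalization -> linear consequents -> weighted sum.
## Training is hybrid by default: consequents by (ridge-regularized) linear
## least squares on the normalized-firing design matrix, premise vertices by
## one gradient step on the training MSE per epoch.

#' Triangular membership degree
#'
#' Membership is 0 outside \code{[left, right]}, 1 at \code{peak}, and
#' linear on each flank.
#'
#' @param x Numeric vector of evaluation points.
#' @param left,peak,right Vertices, \code{left <= peak <= right},
#'   \code{left < right}.
#' @return Membership degrees in \code{[0, 1]}.
#' @export
#' @examples
#' trimf(2, 0, 1, 3)  # 0.5
trimf <- function(x, left, peak, right) {
  if (left > peak || peak > right || left >= right)
    stop("invalid triangular MF vertices", call. = FALSE)
  up <- if (peak > left) (x - left) / (peak - left) else as.numeric(x >= peak)
  dn <- if (right > peak) (right - x) / (right - peak) else as.numeric(x <= peak)
  pmax(0, pmin(up, dn, 1))
}

# Uniform grid partition over [lo, hi]: peaks equispaced, each MF's outer
# vertices at the neighbouring peaks (extended by one grid gap at the ends).
# For 2 MFs this yields (lo - D, lo, hi) and (lo, hi, hi + D) with
# D = hi - lo, so the pair covers the observed range with total membership
# bounded away from zero everywhere on it.
grid_mfs <- function(lo, hi, k) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("degenerate input range [", lo, ", ", hi, "]", call. = FALSE)
  peaks <- seq(lo, hi, length.out = k)
  gap <- if (k > 1) peaks[2L] - peaks[1L] else hi - lo
  cbind(left = c(peaks[1L] - gap, peaks[-k]),
        peak = peaks,
        right = c(peaks[-1L], peaks[k] + gap))
}

#' Initialize an ANFIS by grid partition
#'
#' Places \code{mfs_per_input} triangular membership functions per input by
#' uniform grid partition over the observed range, enumerates every
#' antecedent combination as one rule (so 4 inputs with 2 MFs each give
#' \eqn{2^4 = 16} rules), and zero-initializes the first-order linear
#' consequents (one coefficient per input plus an intercept per rule).
#'
#' @param X Data frame or matrix of training inputs, one column per input.
#' @param mfs_per_input Number of membership functions per input
#'   (default 2).
#' @param standardize Min-max scale each input to \code{[0, 1]} before
#'   partitioning (default \code{TRUE}); the scaling is stored in the model
#'   and applied transparently at prediction time.
#' @return An object of class \code{"anfis"} (untrained).
#' @seealso [anfis()] for the formula interface that also trains the model.
#' @export
anfis_init <- function(X, mfs_per_input = 2, standardize = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("empty training table", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  ranges <- apply(X, 2, range)
  if (any(ranges[1, ] >= ranges[2, ])) {
    bad <- colnames(X)[ranges[1, ] >= ranges[2, ]]
    stop("constant input column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  scaling <- if (standardize) {
    list(center = ranges[1, ], scale = ranges[2, ] - ranges[1, ])
  } else {
    list(center = setNames(rep(0, ncol(X)), colnames(X)),
         scale = setNames(rep(1, ncol(X)), colnames(X)))
  }
  Xs <- scale_inputs(X, scaling)
  k <- rep_len(mfs_per_input, ncol(X))
  mfs <- lapply(seq_len(ncol(X)), function(j)
    grid_mfs(min(Xs[, j]), max(Xs[, j]), k[j]))
  names(mfs) <- colnames(X)
  rules <- as.matrix(rev(expand.grid(rev(lapply(k, seq_len)))))
  dimnames(rules) <- list(NULL, colnames(X))
  structure(list(
    inputs = colnames(X),
    mfs = mfs,
    rules = rules,
    consequents = matrix(0, nrow(rules), ncol(X) + 1L,
                         dimnames = list(NULL, c("c0", colnames(X)))),
    scaling = scaling,
    input_ranges = ranges,
    trace = numeric(0),
    config = list(mfs_per_input = mfs_per_input, standardize = standardize),
    format_version = 1L
  ), class = "anfis")
}

scale_inputs <- function(X, scaling) {
  sweep(sweep(as.matrix(X), 2, scaling$center, "-"), 2, scaling$scale, "/")
}

# n x (per-input MF count) membership degrees on the scaled inputs,
# returned as a list over inputs.
membership_degrees <- function(model, Xs) {
  lapply(seq_along(model$inputs), function(j) {
    mf <- model$mfs[[j]]
    d <- vapply(seq_len(nrow(mf)), function(m)
      trimf(Xs[, j], mf[m, 1], mf[m, 2], mf[m, 3]),
      numeric(nrow(Xs)))
    matrix(d, nrow = nrow(Xs))  # vapply drops to a vector when n = 1
  })
}

#' Membership degrees of an input vector
#'
#' Evaluates every membership function of the model at one input point
#' (layer 1 of the network).  Out-of-range values simply receive degree 0.
#'
#' @param model An \code{"anfis"} object.
#' @param x Named or positional numeric vector, one value per model input.
#' @return A list, one numeric vector of degrees per input.
#' @export
memberships <- function(model, x) {
  X <- input_matrix(model, x)
  deg <- membership_degrees(model, scale_inputs(X, model$scaling))
  names(deg) <- model$inputs
  lapply(deg, function(d) as.numeric(d[1L, , drop = TRUE]))
}

input_matrix <- function(model, x) {
  if (is.null(dim(x))) {
    if (length(x) != length(model$inputs))
      stop("expected ", length(model$inputs), " input values", call. = FALSE)
    x <- matrix(x, nrow = 1L, dimnames = list(NULL, model$inputs))
  }
  x <- as.matrix(x)
  if (!is.null(colnames(x)) && all(model$inputs %in% colnames(x)))
    x <- x[, model$inputs, drop = FALSE]
  x
}

# Raw rule firing strengths (product t-norm): n x n_rules.
firing_strengths <- function(model, Xs) {
  deg <- membership_degrees(model, Xs)
  W <- matrix(1, nrow(Xs), nrow(model$rules))
  for (j in seq_along(model$inputs))
    W <- W * deg[[j]][, model$rules[, j], drop = FALSE]
  W
}

# Per-rule first-order outputs f_i(x) = c_i0 + sum_j c_ij x_j (original
# input units): n x n_rules.
rule_outputs <- function(model, X) {
  cbind(1, X) %*% t(model$consequents)
}

anfis_forward <- function(model, X) {
  X <- input_matrix(model, X)
  Xs <- scale_inputs(X, model$scaling)
  W <- firing_strengths(model, Xs)
  sw <- rowSums(W)
  if (any(sw == 0)) {
    i <- which(sw == 0)[1L]
    stop("no rule fires for input (",
         paste(sprintf("%s = %g", model$inputs, X[i, ]), collapse = ", "),
         "); values lie outside the fuzzified range", call. = FALSE)
  }
  Wn <- W / sw
  list(X = X, Xs = Xs, W = W, sw = sw, Wn = Wn,
       f = rule_outputs(model, X))
}

#' @export
predict.anfis <- function(object, newdata, ...) {
  if (missing(newdata)) return(fitted(object))
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  fw <- anfis_forward(object, newdata)
  as.numeric(rowSums(fw$Wn * fw$f))
}

# Ridge-regularized least squares for the consequents on the blocked design
# Phi = [Wn_i * (1, x)]_i.  lambda = 0 requests the plain minimum-norm
# solution via the pseudoinverse.
solve_consequents <- function(model, X, y, lambda = 1e-6) {
  fw <- anfis_forward(model, X)
  d <- length(model$inputs)
  R <- nrow(model$rules)
  Phi <- matrix(0, nrow(X), R * (d + 1L))
  base <- cbind(1, fw$X)
  for (i in seq_len(R))
    Phi[, ((i - 1L) * (d + 1L) + 1L):(i * (d + 1L))] <- fw$Wn[, i] * base
  coefs <- if (lambda > 0) {
    A <- crossprod(Phi) + diag(lambda, ncol(Phi))
    drop(solve(A, crossprod(Phi, y)))
  } else {
    sv <- svd(Phi)
    pos <- sv$d > max(dim(Phi)) * .Machine$double.eps * sv$d[1L]
    if (!all(pos))
      warning("singular consequent system; using minimum-norm solution")
    drop(sv$v[, pos, drop = FALSE] %*%
           ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos]))
  }
  matrix(coefs, R, d + 1L, byrow = TRUE,
         dimnames = dimnames(model$consequents))
}

# Gradient of the training MSE with respect to the premise vertices, on the
# scaled input space.  Subgradient 0 is used at the non-differentiable
# vertex points.  Returns a list parallel to model$mfs.
premise_gradient <- function(model, fw, y) {
  n <- nrow(fw$X)
  yhat <- rowSums(fw$Wn * fw$f)
  err2 <- 2 * (yhat - y) / n
  deg <- membership_degrees(model, fw$Xs)
  grads <- vector("list", length(model$inputs))
  for (j in seq_along(model$inputs)) {
    mf <- model$mfs[[j]]
    G <- matrix(0, nrow(mf), 3L)
    for (m in seq_len(nrow(mf))) {
      rules_jm <- which(model$rules[, j] == m)
      if (!length(rules_jm)) next
      # d yhat / d mu_{j,m}: sum over rules using MF m at input j of the
      # leave-input-out firing product times (f_i - yhat)/sum(w)
      g_mu <- numeric(n)
      for (i in rules_jm) {
        prod_other <- rep(1, n)
        for (l in seq_along(model$inputs))
          if (l != j)
            prod_other <- prod_other * deg[[l]][, model$rules[i, l]]
        g_mu <- g_mu + (fw$f[, i] - yhat) / fw$sw * prod_other
      }
      x <- fw$Xs[, j]
      a <- mf[m, 1]; b <- mf[m, 2]; cc <- mf[m, 3]
      up <- x > a & x < b      # rising flank
      dn <- x > b & x < cc     # falling flank
      dmu_da <- ifelse(up, (x - b) / (b - a)^2, 0)
      dmu_db <- ifelse(up, -(x - a) / (b - a)^2,
                       ifelse(dn, (cc - x) / (cc - b)^2, 0))
      dmu_dc <- ifelse(dn, (x - b) / (cc - b)^2, 0)
      base <- err2 * g_mu
      G[m, ] <- c(sum(base * dmu_da), sum(base * dmu_db),
                  sum(base * dmu_dc))
    }
    grads[[j]] <- G
  }
  grads
}

clip_vertices <- function(mf) {
  for (m in seq_len(nrow(mf))) {
    v <- sort(mf[m, ])
    if (v[1] >= v[3]) v[3] <- v[1] + .Machine$double.eps * max(1, abs(v[1]))
    mf[m, ] <- v
  }
  mf
}

# Gradient of the MSE with respect to the consequent coefficients (for the
# pure-backpropagation solver).
consequent_gradient <- function(model, fw, y) {
  n <- nrow(fw$X)
  yhat <- rowSums(fw$Wn * fw$f)
  err2 <- 2 * (yhat - y) / n
  crossprod(fw$Wn * err2, cbind(1, fw$X))
}

#' Train an ANFIS
#'
#' Runs \code{epochs} passes over the training data.  With the default
#' \code{solver = "least_squares"} (hybrid learning), each epoch first
#' solves the linear consequent coefficients exactly by ridge-regularized
#' least squares on the normalized-firing design matrix, then takes one
#' gradient-descent step on the premise (membership-vertex) parameters;
#' with \code{solver = "gradient"}, both parameter groups are updated by
#' gradient descent.  Vertex ordering is re-enforced after every update.
#' The returned model carries the per-epoch training mean squared error in
#' \code{$trace}.
#'
#' @param model An \code{"anfis"} object from [anfis_init()].
#' @param X Training inputs (rows match \code{y}).
#' @param y Numeric response vector.
#' @param epochs Number of learning epochs (default 100).
#' @param learning_rate Step size for the premise updates (default 0.05 on
#'   the min-max-scaled input space).
#' @param solver \code{"least_squares"} (hybrid, default) or
#'   \code{"gradient"} (pure backpropagation).
#' @param lambda Ridge penalty for the consequent solve (default
#'   \code{1e-6}); \code{0} requests the exact minimum-norm solution.
#'   With 16 rules and 4 inputs the consequent system has 80 unknowns, so
#'   on small datasets it is underdetermined and the penalty picks the
#'   smallest-coefficient interpolant.
#' @param seed Optional integer seed (reserved for stochastic solver
#'   components; initialization and hybrid training are deterministic).
#' @return The trained \code{"anfis"} model.
#' @export
anfis_train <- function(model, X, y, epochs = 100, learning_rate = 0.05,
                        solver = c("least_squares", "gradient"),
                        lambda = 1e-6, seed = NULL) {
  solver <- match.arg(solver)
  if (!is.numeric(epochs) || epochs < 1)
    stop("epochs must be a positive integer", call. = FALSE)
  epochs <- as.integer(epochs)
  X <- input_matrix(model, X)
  if (nrow(X) != length(y))
    stop("rows of X do not match length of y", call. = FALSE)
  check_finite(y, "y")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    if (solver == "least_squares") {
      model$consequents <- solve_consequents(model, X, y, lambda)
      fw <- anfis_forward(model, X)
      trace[ep] <- mean((rowSums(fw$Wn * fw$f) - y)^2)
      g <- premise_gradient(model, fw, y)
    } else {
      fw <- anfis_forward(model, X)
      trace[ep] <- mean((rowSums(fw$Wn * fw$f) - y)^2)
      gc_ <- consequent_gradient(model, fw, y)
      if (any(!is.finite(gc_)))
        stop("non-finite consequent gradient at epoch ", ep, call. = FALSE)
      model$consequents <- model$consequents - learning_rate * gc_
      g <- premise_gradient(model, fw, y)
    }
    for (j in seq_along(model$mfs)) {
      if (any(!is.finite(g[[j]])))
        stop("non-finite premise gradient at epoch ", ep, " (input ",
             model$inputs[j], ")", call. = FALSE)
      model$mfs[[j]] <- clip_vertices(model$mfs[[j]] -
                                        learning_rate * g[[j]])
    }
  }
  if (solver == "least_squares")  # final consequent solve on updated premises
    model$consequents <- solve_consequents(model, X, y, lambda)
  model$trace <- c(model$trace, trace)
  model$config <- utils::modifyList(model$config, list(
    epochs = epochs, learning_rate = learning_rate, solver = solver,
    lambda = lambda))
  model
}

#' Fit a Takagi-Sugeno neuro-fuzzy model
#'
#' Formula interface for the first-order adaptive neuro-fuzzy inference
#' system: grid-partition initialization ([anfis_init()]) followed by
#' hybrid training ([anfis_train()]).  The default architecture -- two
#' triangular membership functions per input -- gives \eqn{2^d} rules for
#' \eqn{d} inputs, each with a linear consequent in all inputs.
#'
#' @param formula Model formula, e.g. \code{activity ~ A_FC + chi_FC +
#'   I_QB7 + nOH}.
#' @param data Data frame holding the variables.
#' @param mfs_per_input,standardize Passed to [anfis_init()].
#' @param epochs,learning_rate,solver,lambda,seed Passed to
#'   [anfis_train()].
#' @return A trained object of class \code{"anfis"} with the usual
#'   accessors: [predict.anfis()], \code{fitted}, \code{residuals},
#'   \code{coef} (the rule consequent matrix), \code{summary},
#'   \code{plot} (error trace and fit), and \code{simulate}.
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(x1 = runif(60), x2 = runif(60))
#' d$y <- 2 * d$x1 - d$x2 + rnorm(60, sd = 0.05)
#' fit <- anfis(y ~ x1 + x2, d, epochs = 20)
#' summary(fit)
anfis <- function(formula, data, mfs_per_input = 2, epochs = 100,
                  learning_rate = 0.05,
                  solver = c("least_squares", "gradient"), lambda = 1e-6,
                  standardize = TRUE, seed = NULL) {
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X <- as.matrix(mf[, -1L, drop = FALSE])
  model <- anfis_init(X, mfs_per_input = mfs_per_input,
                      standardize = standardize)
  model <- anfis_train(model, X, y, epochs = epochs,
                       learning_rate = learning_rate, solver = solver,
                       lambda = lambda, seed = seed)
  model$call <- match.call()
  model$terms <- terms(mf)
  model$y <- as.numeric(y)
  model$fitted.values <- predict(model, X)
  model$residuals <- model$y - model$fitted.values
  model
}
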