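#' @include AllClasses.R
NULL

#' Z-score standardisation of a samples x variables matrix
#'
#' Columnwise \eqn{(x - mean)/sd} with the sample (n-1) standard
#' deviation.  Constant columns cannot be scaled; they map to all-zero
#' columns and are flagged in the \code{"constant"} attribute rather than
#' dropped, so variable indexing stays stable.
#'
#' @param x numeric matrix, samples in rows (>= 2), variables in columns.
#' @return The scaled matrix with attributes \code{"center"},
#'   \code{"scale"} and \code{"constant"} (logical per column).
#' @export
zscoreMatrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("z-scoring needs at least 2 samples")
  ctr <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  const <- sds == 0 | is.na(sds)
  sds[const] <- 1
  z <- sweep(sweep(x, 2, ctr), 2, sds, "/")
  z[, const] <- 0
  attr(z, "center") <- ctr
  attr(z, "scale") <- ifelse(const, NA_real_, sds)
  attr(z, "constant") <- const
  z
}

#' Principal component analysis by singular value decomposition
#'
#' SVD of the (already centred/scaled) input matrix.  Explained-variance
#' ratios are reported over \emph{all} components and sum to 1; the sign
#' of each component is fixed so that the largest-magnitude loading entry
#' is positive, making outputs bit-stable.
#'
#' @param x numeric matrix, samples in rows; typically a [zscoreMatrix()]
#'   output.  Columns are re-centred defensively.
#' @param nComponents number of components to retain; must not exceed
#'   \code{min(nrow(x) - 1, ncol(x))}.
#' @return List of class \code{"PCAResult"}: \code{scores} (samples x
#'   nComponents), \code{loadings} (variables x nComponents, orthonormal
#'   columns), \code{explainedVariance} (ratio per component, full length).
#' @export
pcaFit <- function(x, nComponents = 2) {
  x <- as.matrix(x)
  kmax <- min(nrow(x) - 1, ncol(x))
  if (nComponents > kmax)
    stop(sprintf("nComponents must be <= min(samples - 1, variables) = %d",
                 kmax))
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  evr <- sv$d^2 / sum(sv$d^2)
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  loadings <- sv$v
  for (a in seq_len(ncol(loadings))) {
    j <- which.max(abs(loadings[, a]))
    if (loadings[j, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  rownames(scores) <- rownames(x)
  rownames(loadings) <- colnames(x)
  colnames(scores) <- colnames(loadings) <-
    paste0("PC", seq_len(ncol(scores)))
  structure(list(scores = scores[, seq_len(nComponents), drop = FALSE],
                 loadings = loadings[, seq_len(nComponents), drop = FALSE],
                 explainedVariance = evr),
            class = "PCAResult")
}

#' Ward hierarchical clustering via the Lance-Williams update
#'
#' Agglomerative clustering of the rows of \code{x} under Ward's
#' minimum-variance criterion with Euclidean distances.  The inter-cluster
#' distance is the Ward distance
#' \eqn{D(A,B) = \sqrt{2 |A||B|/(|A|+|B|)} \, \|c_A - c_B\|}
#' (so \eqn{D^2 = 2 \Delta ESS}, twice the increase in within-cluster sum
#' of squares caused by the merge), maintained after each merge by the
#' Lance-Williams recurrence.  Ties are broken towards the
#' lexicographically smallest cluster pair, making the merge sequence
#' deterministic.  Ward with Euclidean distance is reducible, so merge
#' heights are non-decreasing.
#'
#' @param x numeric matrix; rows are the items to cluster (>= 2).
#' @return List of class \code{"HCAResult"}: \code{merge} (an (n-1) x 2
#'   matrix in \code{\link[stats]{hclust}} convention: negative entries
#'   are singletons, positive entries earlier merge rows), \code{height}
#'   (Ward distance at each merge) and \code{size} (merged cluster sizes).
#' @export
hcaWard <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 items to cluster")
  d2 <- as.matrix(stats::dist(x))^2     # squared Euclidean; D^2 for singletons
  size <- rep(1L, n)
  id <- -seq_len(n)                     # hclust labelling
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  msize <- integer(n - 1)
  for (s in seq_len(n - 1)) {
    best <- c(NA_integer_, NA_integer_)
    bestd <- Inf
    act <- which(active)
    for (ii in seq_along(act)[-length(act)]) {
      i <- act[ii]
      js <- act[(ii + 1):length(act)]
      dij <- d2[i, js]
      jmin <- which.min(dij)
      if (dij[jmin] < bestd) {
        bestd <- dij[jmin]
        best <- c(i, js[jmin])
      }
    }
    i <- best[1]; j <- best[2]
    # record in hclust order: singletons (negative) before clusters, else
    # ascending
    a <- id[i]; b <- id[j]
    merge[s, ] <- if (a < b) c(a, b) else c(b, a)
    height[s] <- sqrt(bestd)
    ni <- size[i]; nj <- size[j]
    # Lance-Williams (Ward) on squared distances
    for (k in act) {
      if (k == i || k == j) next
      nk <- size[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * bestd) /
        (ni + nj + nk)
    }
    size[i] <- ni + nj
    msize[s] <- ni + nj
    id[i] <- s
    active[j] <- FALSE
  }
  structure(list(merge = merge, height = height, size = msize),
            class = "HCAResult")
}

# squared Euclidean distances from rows of x to rows of centers
.dist2centers <- function(x, centers) {
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, "+") - 2 * x %*% t(centers)
}

.kmeansPP <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) {
    mind2 <- .dist2centers(x, centers[1, , drop = FALSE])[, 1]
    for (j in 2:k) {
      mind2 <- pmax(mind2, 0)
      pick <- if (sum(mind2) == 0) sample.int(n, 1)
              else sample.int(n, 1, prob = mind2)
      centers[j, ] <- x[pick, ]
      mind2 <- pmin(mind2, .dist2centers(x, centers[j, , drop = FALSE])[, 1])
    }
  }
  centers
}

#' K-means clustering with the WCSS objective
#'
#' Lloyd iterations from k-means++ initialisation, best of
#' \code{nRestarts} by the within-cluster sum of squared Euclidean
#' distances (WCSS).  Nearest-centre ties break towards the lowest centre
#' index; an emptied cluster is re-seeded with the point farthest from its
#' centre.  Randomness is controlled entirely by \code{seed}.
#'
#' @param x numeric matrix; rows are items.
#' @param k number of clusters, \code{k <= nrow(x)}.
#' @param seed integer seed (mandatory; never wall-clock).
#' @param nRestarts number of k-means++ restarts (default 50).
#' @return List of class \code{"KMeansResult"}: \code{labels} (1..k per
#'   item), \code{centers} (k x variables), \code{wcss} (final objective)
#'   and \code{wcssTrace} (objective after each Lloyd assignment step of
#'   the winning restart; non-increasing).
#' @export
kmeansLloyd <- function(x, k, seed, nRestarts = 50) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k must not exceed the number of items")
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(nRestarts)) {
    centers <- .kmeansPP(x, k)
    labels <- rep(0L, n)
    trace <- numeric(0)
    repeat {
      d2 <- .dist2centers(x, centers)
      newlab <- max.col(-d2, ties.method = "first")
      trace <- c(trace, sum(d2[cbind(seq_len(n), newlab)]))
      for (j in seq_len(k)) {
        if (!any(newlab == j)) {          # re-seed an empty cluster
          far <- which.max(d2[cbind(seq_len(n), newlab)])
          centers[j, ] <- x[far, ]
          newlab[far] <- j
        }
      }
      if (identical(newlab, labels)) break
      labels <- newlab
      for (j in seq_len(k))
        centers[j, ] <- colMeans(x[labels == j, , drop = FALSE])
    }
    wcss <- sum(.dist2centers(x, centers)[cbind(seq_len(n), labels)])
    if (is.null(best) || wcss < best$wcss)
      best <- list(labels = labels, centers = centers, wcss = wcss,
                   wcssTrace = trace)
  }
  structure(best, class = "KMeansResult")
}

#' Two-class OPLS-DA
#'
#' Orthogonal projections to latent structures discriminant analysis with
#' exactly one predictive component (the two-class case) and
#' \code{nOrtho} orthogonal components, fitted by sequential orthogonal
#' signal correction: each round computes the PLS weight
#' \eqn{w \propto X'y}, score \eqn{t = Xw} and loading
#' \eqn{p = X't/(t't)}, extracts the y-orthogonal part of the loading
#' \eqn{w_o \propto p - (w'p)w}, and deflates
#' \eqn{X \leftarrow X - t_o p_o'} with \eqn{t_o = X w_o}.  The final
#' predictive component is fitted on the filtered matrix.  With
#' \code{nOrtho = 0} the model is exactly single-component PLS1.
#'
#' @param X samples x variables matrix, typically [zscoreMatrix()] output.
#' @param y two-class labels (factor, character or numeric), one per row
#'   of \code{X}; coded as centred +/-1 internally (first sorted level is
#'   -1).
#' @param nOrtho number of orthogonal components (default 1).
#' @return An [OPLSFit-class].
#' @export
oplsDA <- function(X, y, nOrtho = 1) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("OPLS-DA needs at least 3 samples")
  yl <- as.character(y)
  classes <- sort(unique(yl))
  if (length(classes) != 2)
    stop("y must contain exactly two classes")
  yc <- ifelse(yl == classes[2], 1, -1)
  yc <- yc - mean(yc)
  ssX <- sum(X^2)
  Xf <- X
  p_vars <- ncol(X)
  To <- matrix(0, nrow(X), 0)
  Wo <- Po <- matrix(0, p_vars, 0)
  ssOrtho <- 0
  for (a in seq_len(nOrtho)) {
    w <- drop(crossprod(Xf, yc))
    nw <- sqrt(sum(w^2))
    if (nw == 0) stop("X carries no covariance with the class labels")
    w <- w / nw
    t <- drop(Xf %*% w)
    p <- drop(crossprod(Xf, t)) / sum(t^2)
    wo <- p - sum(w * p) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break       # no y-orthogonal structure left
    wo <- wo / nwo
    to <- drop(Xf %*% wo)
    po <- drop(crossprod(Xf, to)) / sum(to^2)
    Xf <- Xf - tcrossprod(to, po)
    To <- cbind(To, to)
    Wo <- cbind(Wo, wo)
    Po <- cbind(Po, po)
    ssOrtho <- ssOrtho + sum(to^2) * sum(po^2)
  }
  w <- drop(crossprod(Xf, yc))
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("X carries no covariance with the class labels")
  w <- w / nw
  t <- drop(Xf %*% w)
  p <- drop(crossprod(Xf, t)) / sum(t^2)
  b <- sum(yc * t) / sum(t^2)
  r2y <- 1 - sum((yc - b * t)^2) / sum(yc^2)
  r2x <- (sum(t^2) * sum(p^2) + ssOrtho) / ssX
  vip <- sqrt(p_vars) * abs(w)          # predictive component only
  fit <- new("OPLSFit",
             scores = t, weights = w, loadings = p, yloading = b,
             orthoScores = To, orthoWeights = Wo, orthoLoadings = Po,
             R2X = r2x, R2Y = r2y, vip = unname(vip),
             nOrtho = ncol(To), y = yc, classes = classes,
             permutationP = NA_real_)
  names(fit@vip) <- colnames(X)
  fit
}

#' VIP scores of a fitted OPLS-DA model
#'
#' Variable importance in projection,
#' \deqn{VIP_j = \sqrt{p \; \Sigma_a SSY_a (w_{ja}/\|w_a\|)^2 / \Sigma_a SSY_a},}
#' the weighted sum of squares of the normalised PLS weights with weights
#' equal to the Y-variance explained by each component.  By default only
#' the predictive component enters (the dominant convention for OPLS-DA
#' VIP, under which the formula reduces to
#' \eqn{VIP_j = \sqrt{p}\,|w_j|/\|w\|} and \eqn{\Sigma_j VIP_j^2 = p});
#' \code{orthogonal = TRUE} additionally weights in the orthogonal
#' components by their (typically negligible) explained Y-variance.
#'
#' @param model an [OPLSFit-class] from [oplsDA()].
#' @param orthogonal include orthogonal components (default \code{FALSE}).
#' @return Named numeric vector of VIP scores; \code{mean(VIP^2) = 1}.
#' @export
vipScores <- function(model, orthogonal = FALSE) {
  if (!orthogonal || model@nOrtho == 0) return(model@vip)
  p <- length(model@weights)
  yc <- model@y
  ssy <- function(t) {
    b <- sum(yc * t) / sum(t^2)
    sum(yc^2) - sum((yc - b * t)^2)
  }
  W <- cbind(model@weights, model@orthoWeights)
  Ts <- cbind(model@scores, model@orthoScores)
  ssya <- apply(Ts, 2, ssy)
  wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  v <- sqrt(p * colSums(t(wn^2) * ssya) / sum(ssya))
  stats::setNames(v, names(model@vip))
}

#' Project new samples through a fitted OPLS-DA model
#'
#' Applies the fitted orthogonal filters to \code{Xnew} and returns the
#' predicted (centred) class code \eqn{\hat y = b \, t}.
#'
#' @param fit an [OPLSFit-class].
#' @param Xnew samples x variables matrix on the training scale.
#' @return Numeric predictions, one per row of \code{Xnew}.
#' @export
oplsPredict <- function(fit, Xnew) {
  Xnew <- matrix(Xnew, ncol = length(fit@weights))
  for (a in seq_len(fit@nOrtho)) {
    to <- Xnew %*% fit@orthoWeights[, a, drop = FALSE]
    Xnew <- Xnew - to %*% t(fit@orthoLoadings[, a, drop = FALSE])
  }
  drop(Xnew %*% fit@weights) * fit@yloading
}

#' Leave-one-out Q2 of a two-class OPLS-DA
#'
#' Predictive ability by leave-one-out cross-validation:
#' \eqn{Q^2 = 1 - PRESS / SS_y}, where each held-out sample's class code
#' is predicted from a model fitted to the remaining samples.  Unlike
#' R2Y, which saturates when variables greatly outnumber samples, Q2
#' penalises overfitting and can go negative.
#'
#' @inheritParams oplsDA
#' @return The Q2 statistic.
#' @export
q2LOO <- function(X, y, nOrtho = 1) {
  X <- as.matrix(X)
  yl <- as.character(y)
  classes <- sort(unique(yl))
  if (length(classes) != 2) stop("y must contain exactly two classes")
  yraw <- ifelse(yl == classes[2], 1, -1)
  yc <- yraw - mean(yraw)
  press <- 0
  for (i in seq_len(nrow(X))) {
    fit <- tryCatch(oplsDA(X[-i, , drop = FALSE], yl[-i], nOrtho),
                    error = function(e) NULL)
    pred <- if (is.null(fit)) 0 else oplsPredict(fit, X[i, , drop = FALSE])
    truth <- if (is.null(fit)) yc[i]
             else (if (yl[i] == fit@classes[2]) 1 else -1) - mean(
               ifelse(yl[-i] == fit@classes[2], 1, -1))
    press <- press + (truth - pred)^2
  }
  1 - press / sum(yc^2)
}

#' Permutation validation of an OPLS-DA model
#'
#' Refits the model under \code{nPerm} random permutations of the class
#' labels and reports
#' \deqn{p = (1 + \#\{S_{perm} \ge S_{obs}\}) / (1 + nPerm)}
#' for the chosen statistic \eqn{S}.  R2Y is the default; note that with
#' many more variables than samples R2Y saturates near 1 for any labels,
#' making the test conservative -- the leave-one-out [q2LOO()] statistic
#' is the sharper choice there.
#'
#' @inheritParams oplsDA
#' @param nPerm number of label permutations (>= 1).
#' @param seed integer seed for the permutation stream.
#' @param statistic \code{"R2Y"} (default) or \code{"Q2"}.
#' @return The permutation p-value, with attributes \code{"observed"}
#'   (the observed statistic) and \code{"null"} (the permuted ones).
#' @export
permutationTest <- function(X, y, nOrtho = 1, nPerm = 1000, seed = 1,
                            statistic = c("R2Y", "Q2")) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  statistic <- match.arg(statistic)
  stat <- function(yy)
    if (statistic == "R2Y") oplsDA(X, yy, nOrtho)@R2Y
    else q2LOO(X, yy, nOrtho)
  obs <- stat(y)
  set.seed(as.integer(seed))
  null <- vapply(seq_len(nPerm), function(b) {
    yp <- sample(as.character(y))
    tryCatch(stat(yp), error = function(e) Inf)
  }, numeric(1))
  p <- (1 + sum(null >= obs)) / (1 + nPerm)
  attr(p, "observed") <- obs
  attr(p, "null") <- null
  p
}
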