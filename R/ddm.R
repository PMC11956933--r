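#' Drift-diffusion model parameters
#'
#' Boundary height \code{a} (evidence units), drift rate \code{v} (evidence
#' per second, signed toward the left/upper boundary), non-decision onset
#' time \code{t} (s) and relative starting point \code{z} in (0, 1).  The
#' diffusion coefficient is fixed at 1.
#'
#' @slot a,v,t,z Numeric scalars.
#' @export
setClass("DdmParams", representation(a = "numeric", v = "numeric",
                                     t = "numeric", z = "numeric"))

setValidity("DdmParams", function(object) {
  msgs <- character(0)
  if (object@a <= 0) msgs <- c(msgs, "a must be > 0")
  if (object@t < 0) msgs <- c(msgs, "t must be >= 0")
  if (object@z <= 0 || object@z >= 1) msgs <- c(msgs, "z must be in (0, 1)")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "DdmParams", function(object) {
  cat(sprintf("DdmParams: a = %.3f, v = %.3f, t = %.3f s, z = %.3f\n",
              object@a, object@v, object@t, object@z))
})

#' Construct drift-diffusion parameters
#' @param a Boundary height (> 0).
#' @param v Drift rate (signed toward left).
#' @param t Onset (non-decision) time, s.
#' @param z Starting point as a fraction of a, in (0, 1).
#' @return A \linkS4class{DdmParams}.
#' @export
ddmParams <- function(a, v, t, z = 0.5) {
  obj <- new("DdmParams", a = a, v = v, t = t, z = z)
  validObject(obj)
  obj
}

#' Numeric vector view of DDM parameters
#' @param params A \linkS4class{DdmParams}.
#' @return Named numeric (a, v, t, z).
#' @export
ddmVector <- function(params)
  c(a = params@a, v = params@v, t = params@t, z = params@z)

#' Closed-form probability of absorption at the left (upper) boundary
#' @param params A \linkS4class{DdmParams}.
#' @return P(left) = (exp(-2 v z a) - 1) / (exp(-2 v a) - 1), or z for
#'   v = 0.
#' @export
ddmChoiceProbability <- function(params) {
  v <- params@v; a <- params@a; z <- params@z
  if (abs(v) < 1e-12) return(z)
  expm1(-2 * v * z * a) / expm1(-2 * v * a)
}

#' Simulate choices and response times from the drift-diffusion model
#'
#' Euler-Maruyama integration of unit-diffusion evidence from \code{z * a}
#' between absorbing boundaries 0 and \code{a}; absorption at \code{a} is a
#' left choice.  The response time is the first-passage time plus the onset
#' time \code{t}.
#'
#' @param params A \linkS4class{DdmParams}.
#' @param n Number of trials (>= 1).
#' @param seed Integer seed.
#' @param dtSim Integration step in seconds (<= 0.001).
#' @param maxTime Guard on the first-passage time (s).
#' @return data.frame(choice, rt) with choice in left/right and rt in
#'   seconds.
#' @export
simulateDdm <- function(params, n, seed = 1L, dtSim = 1e-3, maxTime = 30) {
  if (n <= 0) stop("n must be >= 1")
  if (dtSim > 1e-3) stop("dtSim must be <= 1 ms")
  validObject(params)
  set.seed(as.integer(seed))
  a <- params@a; v <- params@v
  x <- rep(params@z * a, n)
  rt <- rep(NA_real_, n)
  choice <- rep(NA_character_, n)
  active <- seq_len(n)
  sdt <- sqrt(dtSim)
  step <- 0L
  maxSteps <- ceiling(maxTime / dtSim)
  while (length(active) && step < maxSteps) {
    step <- step + 1L
    x[active] <- x[active] + v * dtSim + sdt * stats::rnorm(length(active))
    up <- active[x[active] >= a]
    dn <- active[x[active] <= 0]
    if (length(up)) { rt[up] <- step * dtSim; choice[up] <- "left" }
    if (length(dn)) { rt[dn] <- step * dtSim; choice[dn] <- "right" }
    active <- setdiff(active, c(up, dn))
  }
  if (length(active)) {
    rt[active] <- maxTime
    choice[active] <- ifelse(x[active] >= a / 2, "left", "right")
    warning(length(active), " trial(s) hit the simulation time guard")
  }
  data.frame(choice = choice, rt = rt + params@t)
}

# First-passage density at the LOWER boundary for unit diffusion, boundary
# separation a, relative start w, drift v; truncated-series evaluation with
# the small-time / large-time switch chosen by whichever expansion needs
# fewer terms at the requested accuracy.
.wfptLower <- function(t, v, a, w, eps = 1e-7) {
  vapply(t, function(tt) {
    if (!is.finite(tt) || tt <= 0) return(0)
    tn <- tt / a^2  # normalized time
    # terms needed by each expansion (standard accuracy criterion)
    if (pi * tn * eps < 1) {
      kl <- sqrt(-2 * log(pi * tn * eps) / (pi^2 * tn))
      kl <- max(kl, 1 / (pi * sqrt(tn)))
    } else kl <- 1 / (pi * sqrt(tn))
    if (2 * sqrt(2 * pi * tn) * eps < 1) {
      ks <- 2 + sqrt(-2 * tn * log(2 * sqrt(2 * pi * tn) * eps))
      ks <- max(ks, sqrt(tn) + 1)
    } else ks <- 2
    if (ks < kl) {
      K <- ceiling(ks)
      k <- seq(-floor((K - 1) / 2), ceiling((K - 1) / 2))
      f <- sum((w + 2 * k) * exp(-((w + 2 * k)^2) / (2 * tn))) /
        sqrt(2 * pi * tn^3)
    } else {
      K <- ceiling(kl)
      k <- seq_len(K)
      f <- pi * sum(k * exp(-k^2 * pi^2 * tn / 2) * sin(k * pi * w))
    }
    max(f, 0) * exp(-v * a * w - v^2 * tt / 2) / a^2
  }, numeric(1))
}

#' First-passage time density of the drift-diffusion model
#'
#' @param rt Response times (s), including the onset time.
#' @param choice Character vector ("left" = upper boundary, "right" =
#'   lower).
#' @param params A \linkS4class{DdmParams}.
#' @param eps Series truncation tolerance on the density.
#' @return Density values (0 for rt <= t).
#' @export
ddmDensity <- function(rt, choice, params, eps = 1e-7) {
  td <- rt - params@t
  out <- numeric(length(rt))
  left <- choice == "left"
  # upper boundary: reflect (v, w) -> (-v, 1 - w)
  out[left] <- .wfptLower(td[left], -params@v, params@a, 1 - params@z, eps)
  out[!left] <- .wfptLower(td[!left], params@v, params@a, params@z, eps)
  out
}

# EZ-style moment estimates (unit diffusion) used to start the optimizer.
.ezStart <- function(choice, rt) {
  pc <- mean(choice == "left")
  pc <- min(max(pc, 1 / (2 * length(rt))), 1 - 1 / (2 * length(rt)))
  if (abs(pc - 0.5) < 1e-4) pc <- 0.5 + 1e-4
  vrt <- stats::var(rt)
  mrt <- mean(rt)
  L <- stats::qlogis(pc)
  x <- L * (L * pc^2 - L * pc + pc - 0.5) / vrt
  v <- sign(pc - 0.5) * abs(x)^(1 / 4)
  if (!is.finite(v) || v == 0) v <- 1e-3 * sign(pc - 0.5 + 1e-9)
  a <- L / v
  if (!is.finite(a) || a <= 0) a <- 1
  mdt <- (a / (2 * v)) * (1 - exp(-v * a)) / (1 + exp(-v * a))
  t0 <- mrt - mdt
  t0 <- min(max(t0, 0), 0.95 * min(rt))
  c(a = a, v = v, t = t0)
}

#' Maximum-likelihood fit of the drift-diffusion model
#'
#' Fits (a, v, t, z) by maximizing the truncated-series first-passage
#' likelihood with a Nelder-Mead simplex started from moment-based
#' estimates; bounds are enforced by transform (log a, logit of t relative
#' to the fastest response, logit z).
#'
#' @param choice Character vector of "left"/"right" choices (trials with
#'   other values are dropped).
#' @param rt Response times in seconds (must exceed the fitted onset time).
#' @param fixZ Optional fixed starting bias (fit z freely when NULL).
#' @param eps Density series tolerance.
#' @return A \code{DdmFit}: slots \code{params}
#'   (\linkS4class{DdmParams}), \code{loglik}, \code{converged},
#'   \code{flags} (character), \code{n}.
#' @export
fitDdm <- function(choice, rt, fixZ = NULL, eps = 1e-7) {
  keep <- choice %in% c("left", "right") & is.finite(rt)
  choice <- choice[keep]; rt <- rt[keep]
  n <- length(rt)
  if (n < 2L) stop("at least 2 usable trials are required")
  flags <- character(0)
  if (n < 50L) flags <- c(flags, "small_sample")
  if (all(choice == choice[1])) {
    warning("all trials share one choice; v and z are weakly identified")
    flags <- c(flags, "one_choice_wide")
  }
  minRt <- min(rt)
  start <- .ezStart(choice, rt)
  freeZ <- is.null(fixZ)

  unpack <- function(theta) {
    a <- exp(theta[1]); v <- theta[2]
    t0 <- 0.999 * minRt * stats::plogis(theta[3])
    z <- if (freeZ) stats::plogis(theta[4]) else fixZ
    list(a = a, v = v, t = t0, z = z)
  }
  nll <- function(theta) {
    p <- unpack(theta)
    d <- ddmDensity(rt, choice, new("DdmParams", a = p$a, v = p$v,
                                    t = p$t, z = p$z), eps = eps)
    if (any(d <= 0) || any(!is.finite(d))) return(1e10)
    -sum(log(d))
  }
  t3 <- stats::qlogis(min(max(start[["t"]] / (0.999 * minRt), 0.02), 0.98))
  theta0 <- c(log(max(start[["a"]], 0.05)), start[["v"]], t3)
  if (freeZ) theta0 <- c(theta0, 0)
  opt <- stats::optim(theta0, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-9))
  p <- unpack(opt$par)
  params <- new("DdmParams", a = p$a, v = p$v, t = p$t, z = p$z)
  validObject(params)
  conv <- opt$convergence == 0
  if (!conv) flags <- c(flags, "optimizer_not_converged")
  new("DdmFit", params = params, loglik = -opt$value,
      converged = conv, flags = flags, n = as.integer(n))
}

#' Fitted drift-diffusion model with diagnostics
#' @slot params A \linkS4class{DdmParams}.
#' @slot loglik Maximized log-likelihood.
#' @slot converged Logical optimizer status.
#' @slot flags Character vector of fit warnings.
#' @slot n Number of fitted trials.
#' @export
setClass("DdmFit", representation(params = "DdmParams", loglik = "numeric",
                                  converged = "logical", flags = "character",
                                  n = "integer"))

setMethod("show", "DdmFit", function(object) {
  p <- ddmVector(object@params)
  cat(sprintf("DdmFit (n = %d): a = %.3f, v = %.3f, t = %.3f, z = %.3f\n",
              object@n, p["a"], p["v"], p["t"], p["z"]))
  cat(sprintf("  loglik %.2f, converged %s%s\n", object@loglik,
              object@converged,
              if (length(object@flags))
                paste0(", flags: ", paste(object@flags, collapse = ", "))
              else ""))
})
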