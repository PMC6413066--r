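#' Swarm optimizer configuration
#'
#' Configures PSO, QPSO or EQPSO over a bounded search space.  QPSO places
#' every particle at a stochastic distance from its local attractor, scaled
#' by the contraction-expansion factor and the spread `|M - x|` around the
#' mean-best position `M`; EQPSO adds three enhancements aimed at diverse
#' early search and strong late local search: a linearly decreasing
#' contraction-expansion schedule, an elitist (fitness-rank-weighted)
#' mean-best position, and a Gaussian kick of the global best after
#' `stagnation_limit` improvement-free iterations.  Each enhancement is a
#' flag, so plain QPSO is the same code with all three disabled.
#'
#' @param n_dim Dimensionality of the search space.
#' @param n_particles Swarm size (>= 1).
#' @param n_iter Iterations.
#' @param strategy `"eqpso"`, `"qpso"` or `"pso"`.
#' @param c1,c2 Acceleration constants (attractor mixing; PSO velocity).
#' @param ce_start,ce_end Contraction-expansion factor at the first and
#'   last iteration.  Defaults: constant 0.75 for QPSO; 1.0 decreasing to
#'   0.5 for EQPSO.
#' @param inertia PSO velocity inertia (constriction-style constant 0.72).
#' @param lower,upper Per-dimension bounds (scalars recycle).
#' @param elitist_mean Weight mean-best by fitness rank (EQPSO).
#' @param ce_schedule Linearly interpolate `ce_start -> ce_end` (EQPSO);
#'   otherwise `ce_start` is used throughout.
#' @param perturb_gbest Gaussian kick of the global best on stagnation
#'   (EQPSO).
#' @param stagnation_limit Iterations without improvement before the kick.
#' @param seed Integer seed.
#' @return Object of class `swarm_config`.
#' @export
swarm_config <- function(n_dim, n_particles = 30, n_iter = 100,
                         strategy = c("eqpso", "qpso", "pso"),
                         c1 = 2, c2 = 2,
                         ce_start = NULL, ce_end = NULL,
                         inertia = 0.72,
                         lower = -5, upper = 5,
                         elitist_mean = NULL, ce_schedule = NULL,
                         perturb_gbest = NULL, stagnation_limit = 10,
                         seed = 1L) {
  strategy <- match.arg(strategy)
  if (n_particles < 1) stop("n_particles must be >= 1", call. = FALSE)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  if (c1 <= 0 || c2 <= 0) stop("c1 and c2 must be positive", call. = FALSE)
  eq <- strategy == "eqpso"
  if (is.null(ce_start)) ce_start <- if (eq) 1.0 else 0.75
  if (is.null(ce_end)) ce_end <- if (eq) 0.5 else ce_start
  if (ce_start <= 0 || ce_end <= 0)
    stop("contraction-expansion factors must be positive", call. = FALSE)
  if (is.null(elitist_mean)) elitist_mean <- eq
  if (is.null(ce_schedule)) ce_schedule <- eq
  if (is.null(perturb_gbest)) perturb_gbest <- eq
  lower <- rep_len(lower, n_dim); upper <- rep_len(upper, n_dim)
  if (any(lower >= upper)) stop("lower must be < upper", call. = FALSE)
  structure(list(n_dim = as.integer(n_dim),
                 n_particles = as.integer(n_particles),
                 n_iter = as.integer(n_iter), strategy = strategy,
                 c1 = c1, c2 = c2, ce_start = ce_start, ce_end = ce_end,
                 inertia = inertia, lower = lower, upper = upper,
                 elitist_mean = elitist_mean, ce_schedule = ce_schedule,
                 perturb_gbest = perturb_gbest,
                 stagnation_limit = as.integer(stagnation_limit),
                 seed = as.integer(seed)),
            class = "swarm_config")
}

#' Local attractor of a particle
#'
#' Convex combination `phi * p_i + (1 - phi) * p_g` with
#' `phi = c1 r1 / (c1 r1 + c2 r2)`, mixing the personal best `p_i` and the
#' global best `p_g`.  When `c1 r1 + c2 r2 = 0` the midpoint is used.
#'
#' @param p_i,p_g Personal-best and global-best positions (vectors).
#' @param c1,c2 Acceleration constants.
#' @param r1,r2 Uniform random draws in `[0, 1]` (scalars or per-dimension).
#' @return Attractor point.
#' @export
local_attractor <- function(p_i, p_g, c1, c2, r1, r2) {
  a <- c1 * r1; b <- c2 * r2
  phi <- ifelse(a + b == 0, 0.5, a / (a + b))
  phi * p_i + (1 - phi) * p_g
}

#' One QPSO position update for the whole swarm
#'
#' Every coordinate moves to
#' `attractor +/- ce * |M - x| * ln(1/u)` with `u ~ U(0, 1)` and the sign
#' equiprobable, where the attractor is [local_attractor()] of the personal
#' and global bests and `M` is the mean-best position.  Positions are
#' clipped to the bounds.  Draws come from the current RNG stream.
#'
#' @param positions,pbest Matrices `P x D` of current positions and
#'   personal bests.
#' @param gbest Global-best position (length `D`).
#' @param mean_best Mean-best position `M` (length `D`).
#' @param ce Contraction-expansion factor (> 0).
#' @param c1,c2 Acceleration constants.
#' @param lower,upper Per-dimension bounds.
#' @return New position matrix `P x D`.
#' @export
qpso_step <- function(positions, pbest, gbest, mean_best, ce, c1, c2,
                      lower, upper) {
  P <- nrow(positions); D <- ncol(positions)
  r1 <- matrix(stats::runif(P * D), P, D)
  r2 <- matrix(stats::runif(P * D), P, D)
  G <- matrix(gbest, P, D, byrow = TRUE)
  att <- local_attractor(pbest, G, c1, c2, r1, r2)
  u <- matrix(stats::runif(P * D), P, D)
  u[u == 0] <- .Machine$double.eps
  sgn <- matrix(sample(c(-1, 1), P * D, replace = TRUE), P, D)
  M <- matrix(mean_best, P, D, byrow = TRUE)
  new <- att + sgn * ce * abs(M - positions) * log(1 / u)
  lo <- matrix(lower, P, D, byrow = TRUE)
  hi <- matrix(upper, P, D, byrow = TRUE)
  pmin(pmax(new, lo), hi)
}

#' Decode a particle into pipeline parameters
#'
#' The 19-dimensional encoding of the joint optimization problem: three
#' weight logits (softmax onto the open simplex gives `alpha, beta, gamma`),
#' one kernel-scale coordinate (affine map of the position onto
#' `log(sigma_range)`, then exponentiated), and 15 sensor bits (bit = 1 iff
#' the coordinate is positive).  A particle selecting no sensor at all is
#' flagged invalid; the optimizer assigns it fitness `-Inf`.
#'
#' @param position Numeric vector (3 + 1 + `n_bits` entries).
#' @param lower,upper Bounds of the kernel-scale coordinate's dimension
#'   (dimension 4), used for the affine map.
#' @param sigma_range Kernel-scale range, default `c(1e-2, 1e3)`.
#' @param n_bits Number of sensor bits (default 15).
#' @return List with `weights` ([objective_weights()] or `NULL` when
#'   degenerate), `sigma`, `bits` (logical), `valid`, `position`.
#' @export
decode_particle <- function(position, lower = -5, upper = 5,
                            sigma_range = c(1e-2, 1e3), n_bits = 15) {
  stopifnot(length(position) >= 4 + n_bits)
  z <- position[1:3] - max(position[1:3])
  w <- exp(z) / sum(exp(z))
  weights <- tryCatch(objective_weights(w[1], w[2], w[3]),
                      error = function(e) NULL)
  lo4 <- rep_len(lower, 4)[4]; hi4 <- rep_len(upper, 4)[4]
  s01 <- min(max((position[4] - lo4) / (hi4 - lo4), 0), 1)
  sigma <- exp(log(sigma_range[1]) +
                 s01 * (log(sigma_range[2]) - log(sigma_range[1])))
  bits <- position[4 + seq_len(n_bits)] > 0
  list(weights = weights, sigma = sigma, bits = bits,
       valid = any(bits) && !is.null(weights), position = position)
}

#' Run a particle-swarm optimization
#'
#' Maximizes `fitness(decoded)` over the configured space with the selected
#' strategy.  The decoder maps raw positions to the argument handed to the
#' fitness function; decodes flagged invalid receive fitness `-Inf`.  The
#' best-so-far trace is non-decreasing and the whole run is reproducible
#' under the config seed.  The fitness must be deterministic given its
#' argument (fix any internal seeds).
#'
#' @param fitness Function of one argument (the decoded particle) returning
#'   a scalar to maximize.
#' @param config A [swarm_config()].
#' @param decode Function mapping a raw position vector to the fitness
#'   argument; defaults to the identity (the raw position, with `valid`
#'   always true).  Use [decode_particle()] for the E-nose encoding.
#' @param init Optional matrix of starting positions (one row per particle)
#'   overriding the uniform initialization of the first `nrow(init)`
#'   particles — e.g. a warm start at an incumbent configuration.
#' @return List with `best` (decoded best particle), `best_fitness`,
#'   `history` (best fitness per iteration), `positions`, `pbest`,
#'   `pbest_fitness`.
#' @export
swarm_optimize <- function(fitness, config,
                           decode = function(p) list(position = p,
                                                     valid = TRUE),
                           init = NULL) {
  stopifnot(inherits(config, "swarm_config"))
  set.seed(config$seed)
  P <- config$n_particles; D <- config$n_dim
  lo <- config$lower; hi <- config$upper
  positions <- matrix(stats::runif(P * D), P, D)
  positions <- sweep(sweep(positions, 2, hi - lo, "*"), 2, lo, "+")
  if (!is.null(init)) {
    init <- matrix(init, ncol = D)
    k <- min(nrow(init), P)
    positions[seq_len(k), ] <- pmin(pmax(init[seq_len(k), , drop = FALSE],
                                         matrix(lo, k, D, byrow = TRUE)),
                                    matrix(hi, k, D, byrow = TRUE))
  }
  velocities <- matrix(0, P, D)

  eval_particle <- function(pos) {
    dec <- decode(pos)
    if (!isTRUE(dec$valid)) return(list(fit = -Inf, dec = dec))
    list(fit = fitness(dec), dec = dec)
  }

  pbest <- positions
  pbest_fit <- numeric(P)
  decs <- vector("list", P)
  for (i in seq_len(P)) {
    ev <- eval_particle(positions[i, ])
    pbest_fit[i] <- ev$fit; decs[[i]] <- ev$dec
  }
  gi <- which.max(pbest_fit)
  gbest <- pbest[gi, ]; gbest_fit <- pbest_fit[gi]; gbest_dec <- decs[[gi]]
  history <- numeric(config$n_iter)
  stagnant <- 0L

  for (it in seq_len(config$n_iter)) {
    ce <- if (config$ce_schedule && config$n_iter > 1) {
      config$ce_start + (config$ce_end - config$ce_start) *
        (it - 1) / (config$n_iter - 1)
    } else config$ce_start
    if (config$strategy == "pso") {
      r1 <- matrix(stats::runif(P * D), P, D)
      r2 <- matrix(stats::runif(P * D), P, D)
      G <- matrix(gbest, P, D, byrow = TRUE)
      velocities <- config$inertia * velocities +
        config$c1 * r1 * (pbest - positions) +
        config$c2 * r2 * (G - positions)
      positions <- positions + velocities
      positions <- pmin(pmax(positions,
                             matrix(lo, P, D, byrow = TRUE)),
                        matrix(hi, P, D, byrow = TRUE))
    } else {
      mean_best <- if (config$elitist_mean && P > 1) {
        rk <- rank(pbest_fit, ties.method = "first")   # best gets weight P
        wts <- rk / sum(rk)
        colSums(pbest * wts)
      } else colMeans(pbest)
      positions <- qpso_step(positions, pbest, gbest, mean_best, ce,
                             config$c1, config$c2, lo, hi)
    }
    improved <- FALSE
    for (i in seq_len(P)) {
      ev <- eval_particle(positions[i, ])
      if (ev$fit > pbest_fit[i]) {
        pbest_fit[i] <- ev$fit; pbest[i, ] <- positions[i, ]
        decs[[i]] <- ev$dec
      }
      if (ev$fit > gbest_fit) {
        gbest_fit <- ev$fit; gbest <- positions[i, ]; gbest_dec <- ev$dec
        improved <- TRUE
      }
    }
    stagnant <- if (improved) 0L else stagnant + 1L
    if (config$perturb_gbest && stagnant >= config$stagnation_limit) {
      kick <- gbest + stats::rnorm(D, 0, 0.05 * (hi - lo))
      kick <- pmin(pmax(kick, lo), hi)
      ev <- eval_particle(kick)
      if (ev$fit > gbest_fit) {
        gbest_fit <- ev$fit; gbest <- kick; gbest_dec <- ev$dec
        gi <- which.min(pbest_fit)
        pbest[gi, ] <- kick; pbest_fit[gi] <- ev$fit; decs[[gi]] <- ev$dec
      }
      stagnant <- 0L
    }
    history[it] <- gbest_fit
  }
  list(best = gbest_dec, best_fitness = gbest_fit, history = history,
       positions = positions, pbest = pbest, pbest_fitness = pbest_fit)
}
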