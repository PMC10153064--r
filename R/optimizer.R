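#' Define a gain-optimization problem
#'
#' Sets up the mixed-integer optimization of the feedback gains and
#' prediction time for one muscle-model variant under one criterion:
#' minimise the four-target average of either the stabilisation error or
#' the movement error. The prediction time is a discrete number of
#' simulation steps, making the problem mixed-integer.
#'
#' Default gain bounds envelop the published optima with margin; the
#' prediction-time range spans 0-100 ms.
#'
#' @param variant muscle-model variant name.
#' @param criterion `"stabilisation"` or `"movement"`.
#' @param Kp_bounds,Kv_bounds numeric(2) lower/upper bounds applied to each
#'   gain.
#' @param tau_steps_max largest admissible prediction time in simulation
#'   steps (the range always includes 0).
#' @param pop_size,generations genetic-algorithm budget.
#' @param seed RNG seed for the search.
#' @param init optional list of [control_params()] used to seed the initial
#'   population (e.g. published gains for a warm start / restart).
#' @param penalty objective value (mm) assigned to candidates whose
#'   simulation blows up.
#' @param config optional configuration list passed to [arm_model()].
#' @param targets optional list of [reach_task()]s overriding the four
#'   standard targets (e.g. shortened tasks for quick experimentation).
#' @return An object of class `optimization_problem`.
#' @export
optimization_problem <- function(variant, criterion = c("stabilisation",
                                                        "movement"),
                                 Kp_bounds = c(0, 1e4),
                                 Kv_bounds = c(0, 1e3),
                                 tau_steps_max = 50L,
                                 pop_size = 60L, generations = 100L,
                                 seed = 1L, init = NULL, penalty = 1000,
                                 config = NULL, targets = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(Kp_bounds[1] >= 0, Kp_bounds[2] > Kp_bounds[1],
            Kv_bounds[1] >= 0, Kv_bounds[2] > Kv_bounds[1],
            tau_steps_max >= 0, pop_size >= 2, generations >= 1)
  model <- arm_model(variant, config = config)
  if (is.null(targets)) targets <- make_targets(model$x0)
  structure(list(variant = variant, criterion = criterion,
                 model = model, targets = targets,
                 lower = c(rep(Kp_bounds[1], 3), rep(Kv_bounds[1], 3)),
                 upper = c(rep(Kp_bounds[2], 3), rep(Kv_bounds[2], 3)),
                 tau_steps_max = as.integer(tau_steps_max),
                 pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 seed = as.integer(seed), init = init, penalty = penalty),
            class = "optimization_problem")
}

#' Objective of a gain-optimization problem
#'
#' Simulates the four standard reaches with the candidate control
#' parameters and returns the target-averaged error (mm) selected by the
#' problem's criterion. A simulation blow-up yields the problem's penalty
#' value rather than an error, so the search can continue.
#'
#' @param ctrl a [control_params()] object.
#' @param problem an [optimization_problem()].
#' @return Mean error over the four targets (mm).
#' @export
objective <- function(ctrl, problem) {
  res <- tryCatch(evaluate_controller(problem$model, ctrl, problem$targets),
                  error = function(e) NULL)
  if (is.null(res)) return(problem$penalty)
  1000 * if (problem$criterion == "stabilisation") res$e_st_bar else res$e_mv_bar
}

# genome encoding: 6 continuous gains + 1 integer tau gene
.decode <- function(g, dt) {
  control_params(Kp = g[1:3], Kv = g[4:6], tau = round(g[7]) * dt, dt = dt)
}

#' Optimize feedback gains and prediction time
#'
#' Mixed-integer genetic algorithm: tournament selection, simulated binary
#' crossover and polynomial mutation for the six continuous gains, uniform
#' crossover and uniform-reset mutation for the integer prediction-time
#' gene, with single-candidate elitism. The search is deterministic given
#' the problem's seed. Candidates supplied in `problem$init` are injected
#' into the initial population, supporting warm starts and multi-restart
#' runs.
#'
#' @param problem an [optimization_problem()].
#' @param polish if `TRUE`, the best candidate found by the GA is refined
#'   by a derivative-free Nelder-Mead search over the six continuous gains
#'   with the integer prediction time held at its optimized value (a
#'   standard memetic finishing step; the landscape is noiseless, so local
#'   refinement near the GA optimum is cheap and effective).
#' @param polish_budget maximum objective evaluations for the polish.
#' @return A list with `best` (a [control_params()]), `error` (mm), and
#'   `log` (data.frame with per-generation best-so-far objective and
#'   candidate).
#' @export
optimize_gains <- function(problem, polish = FALSE, polish_budget = 400L) {
  dt <- problem$model$params$dt
  n_cont <- 6
  lo <- problem$lower
  hi <- problem$upper
  P <- problem$pop_size
  set.seed(problem$seed)

  pop <- t(replicate(P, c(stats::runif(n_cont, lo, hi),
                          sample(0:problem$tau_steps_max, 1))))
  if (!is.null(problem$init)) {
    for (i in seq_along(problem$init)) {
      if (i > P) break
      ci <- problem$init[[i]]
      pop[i, ] <- c(pmin(pmax(ci$Kp, lo[1:3]), hi[1:3]),
                    pmin(pmax(ci$Kv, lo[4:6]), hi[4:6]),
                    min(ci$tau_steps, problem$tau_steps_max))
    }
  }

  fitness <- apply(pop, 1, function(g) objective(.decode(g, dt), problem))
  log <- NULL
  sbx_eta <- 10; mut_eta <- 20; p_cross <- 0.9; p_mut <- 1 / 7

  for (gen in seq_len(problem$generations)) {
    ib <- which.min(fitness)
    log <- rbind(log, data.frame(
      generation = gen - 1L, best = fitness[ib],
      Kp1 = pop[ib, 1], Kp2 = pop[ib, 2], Kp3 = pop[ib, 3],
      Kv1 = pop[ib, 4], Kv2 = pop[ib, 5], Kv3 = pop[ib, 6],
      tau_steps = round(pop[ib, 7])))

    newpop <- matrix(0, P, 7)
    newpop[1, ] <- pop[ib, ]  # elitism
    k <- 2
    while (k <= P) {
      # binary tournaments
      pick <- function() {
        ij <- sample.int(P, 2)
        pop[ij[which.min(fitness[ij])], ]
      }
      p1 <- pick(); p2 <- pick()
      c1 <- p1; c2 <- p2
      if (stats::runif(1) < p_cross) {
        # SBX on continuous genes
        for (j in seq_len(n_cont)) {
          uu <- stats::runif(1)
          beta <- if (uu <= 0.5) (2 * uu)^(1 / (sbx_eta + 1)) else
            (1 / (2 * (1 - uu)))^(1 / (sbx_eta + 1))
          c1[j] <- 0.5 * ((1 + beta) * p1[j] + (1 - beta) * p2[j])
          c2[j] <- 0.5 * ((1 - beta) * p1[j] + (1 + beta) * p2[j])
        }
        # uniform crossover on the integer gene
        if (stats::runif(1) < 0.5) { c1[7] <- p2[7]; c2[7] <- p1[7] }
      }
      for (ch in list(1, 2)) {
        cc <- if (ch == 1) c1 else c2
        for (j in seq_len(n_cont)) {
          if (stats::runif(1) < p_mut) {
            uu <- stats::runif(1)
            delta <- if (uu < 0.5) (2 * uu)^(1 / (mut_eta + 1)) - 1 else
              1 - (2 * (1 - uu))^(1 / (mut_eta + 1))
            cc[j] <- cc[j] + delta * (hi[j] - lo[j])
          }
        }
        if (stats::runif(1) < p_mut)
          cc[7] <- sample(0:problem$tau_steps_max, 1)
        cc[1:n_cont] <- pmin(pmax(cc[1:n_cont], lo), hi)
        cc[7] <- min(max(round(cc[7]), 0), problem$tau_steps_max)
        if (ch == 1) c1 <- cc else c2 <- cc
      }
      newpop[k, ] <- c1
      if (k + 1 <= P) newpop[k + 1, ] <- c2
      k <- k + 2
    }
    pop <- newpop
    # the elite is re-evaluated; the objective is deterministic, so the
    # recorded best-so-far can never worsen
    fitness <- apply(pop, 1, function(g) objective(.decode(g, dt), problem))
  }
  ib <- which.min(fitness)
  log <- rbind(log, data.frame(
    generation = problem$generations, best = fitness[ib],
    Kp1 = pop[ib, 1], Kp2 = pop[ib, 2], Kp3 = pop[ib, 3],
    Kv1 = pop[ib, 4], Kv2 = pop[ib, 5], Kv3 = pop[ib, 6],
    tau_steps = round(pop[ib, 7])))
  g <- pop[ib, ]
  err <- fitness[ib]
  if (polish) {
    tau_fixed <- round(g[7])
    f <- function(x) {
      x <- pmin(pmax(x, lo), hi)
      objective(.decode(c(x, tau_fixed), dt), problem)
    }
    opt <- stats::optim(g[1:n_cont], f, method = "Nelder-Mead",
                        control = list(maxit = polish_budget))
    if (opt$value < err) {
      g <- c(pmin(pmax(opt$par, lo), hi), tau_fixed)
      err <- opt$value
      log <- rbind(log, utils::tail(log, 1))
      log[nrow(log), ] <- data.frame(
        generation = problem$generations + 1L, best = err,
        Kp1 = g[1], Kp2 = g[2], Kp3 = g[3],
        Kv1 = g[4], Kv2 = g[5], Kv3 = g[6], tau_steps = tau_fixed)
    }
  }
  list(best = .decode(g, dt), error = err, log = log)
}
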