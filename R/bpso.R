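#' Binary PSO parameters
#'
#' Defaults follow the common wrapper-selection setting for this method:
#' inertia weight `w = 0.4`, acceleration constants `c1 = c2 = 2`, velocity
#' clamp `[-4, 4]`, at most `T = 100` iterations with early stop once the
#' global best fitness reaches `target_fitness = 1`. When `n_particles` is
#' `NULL` it resolves to `max(2, round(n_genes / 100))` at run time.
#'
#' @param n_particles swarm size, or `NULL` to derive from the problem size.
#' @param w inertia weight.
#' @param c1,c2 cognitive and social acceleration constants.
#' @param vmin,vmax velocity bounds (`vmin < vmax`).
#' @param max_iter maximum iterations `T` (>= 1).
#' @param init_one_prob probability a bit initializes to 1 (default 0.5:
#'   each bit is 1 iff a fresh U(0,1) draw exceeds 0.5).
#' @param target_fitness stop as soon as the global best reaches this value.
#' @return a `pso_params` list.
#' @export
pso_params <- function(n_particles = NULL, w = 0.4, c1 = 2, c2 = 2,
                       vmin = -4, vmax = 4, max_iter = 100L,
                       init_one_prob = 0.5, target_fitness = 1.0) {
  if (!(vmin < vmax)) stop_psodt("vmin must be < vmax")
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop_psodt("max_iter must be >= 1")
  if (!is.null(n_particles) && n_particles < 2)
    stop_psodt("n_particles must be >= 2")
  if (init_one_prob < 0 || init_one_prob > 1)
    stop_psodt("init_one_prob must be in [0, 1]")
  structure(list(n_particles = n_particles, w = w, c1 = c1, c2 = c2,
                 vmin = vmin, vmax = vmax, max_iter = max_iter,
                 init_one_prob = init_one_prob,
                 target_fitness = target_fitness),
            class = "pso_params")
}

resolve_n_particles <- function(params, n_genes) {
  if (!is.null(params$n_particles)) return(as.integer(params$n_particles))
  max(2L, as.integer(round(n_genes / 100)))
}

#' Logistic sigmoid
#'
#' `1 / (1 + exp(-v))`, computed in the numerically stable branch form so it
#' stays finite and in (0, 1) for |v| up to several hundred. Maps a particle
#' velocity to the probability that the corresponding bit activates.
#'
#' @param v numeric vector.
#' @return values in (0, 1).
#' @export
sigmoid <- function(v) {
  out <- numeric(length(v))
  pos <- v >= 0
  out[pos] <- 1 / (1 + exp(-v[pos]))
  ev <- exp(v[!pos])
  out[!pos] <- ev / (1 + ev)
  out
}

new_particle <- function(position) {
  list(position = as.integer(position),
       velocity = numeric(length(position)),
       pbest_position = NULL,
       pbest_fitness = NA_real_)
}

#' Initialize a swarm of binary particles
#'
#' Each bit of each particle is set to 1 iff a fresh U(0,1) draw exceeds
#' `1 - init_one_prob` (with the default 0.5 this is the classic
#' "U(0,1) > 0.5" rule). Velocities start at zero; personal bests are unset
#' until the first evaluation.
#'
#' @param n_genes dimensionality (number of genes).
#' @param params a [pso_params].
#' @param runif_fn uniform generator, `function(n) -> n draws in (0,1)`;
#'   replaceable for testing.
#' @return a `swarm_state` list: `particles`, `gbest_position`,
#'   `gbest_fitness`, `iteration`, `history`.
#' @export
init_swarm <- function(n_genes, params = pso_params(), runif_fn = stats::runif) {
  if (n_genes < 1) stop_psodt("n_genes must be >= 1")
  np <- resolve_n_particles(params, n_genes)
  particles <- lapply(seq_len(np), function(i)
    new_particle(runif_fn(n_genes) > 1 - params$init_one_prob))
  structure(list(particles = particles, gbest_position = NULL,
                 gbest_fitness = -Inf, iteration = 0L, history = numeric(0)),
            class = "swarm_state")
}

#' One particle's velocity update
#'
#' Canonical global-best rule
#' `v <- w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)` with fresh per-
#' dimension U(0,1) draws `r1`, `r2` (r1 drawn first), followed by
#' elementwise clamping into `[vmin, vmax]`.
#'
#' @param particle a particle with its personal best set.
#' @param gbest_position current global best bit vector.
#' @param params a [pso_params].
#' @param runif_fn uniform generator (see [init_swarm()]).
#' @return the new clamped velocity vector.
#' @export
update_velocity <- function(particle, gbest_position, params = pso_params(),
                            runif_fn = stats::runif) {
  if (is.null(particle$pbest_position))
    stop_psodt("personal best unset; evaluate the particle before moving it")
  n <- length(particle$position)
  r1 <- runif_fn(n)
  r2 <- runif_fn(n)
  v <- params$w * particle$velocity +
    params$c1 * r1 * (particle$pbest_position - particle$position) +
    params$c2 * r2 * (gbest_position - particle$position)
  pmin(pmax(v, params$vmin), params$vmax)
}

#' One particle's stochastic bit update
#'
#' Each bit is set to 1 iff `sigmoid(v) > u` for a fresh per-dimension
#' U(0,1) draw `u`, using the particle's current (already updated) velocity.
#'
#' @param particle a particle.
#' @param runif_fn uniform generator.
#' @return integer 0/1 vector, the new position.
#' @export
update_position <- function(particle, runif_fn = stats::runif) {
  u <- runif_fn(length(particle$velocity))
  as.integer(sigmoid(particle$velocity) > u)
}

#' Advance the swarm by one iteration
#'
#' In particle order: evaluate the fitness of the current position, update
#' the personal best on strict improvement (ties keep the old best), and
#' update the global best on strict improvement (so among particles
#' improving in the same sweep the lowest index wins). After the evaluation
#' sweep every particle's velocity and position are updated for the next
#' iteration. The iteration counter advances and the global best fitness is
#' appended to the history.
#'
#' @param swarm a `swarm_state`.
#' @param fitness_fn `function(position) -> fitness in [0, 1]`.
#' @param params a [pso_params].
#' @param runif_fn uniform generator.
#' @return the updated `swarm_state`.
#' @export
pso_step <- function(swarm, fitness_fn, params = pso_params(),
                     runif_fn = stats::runif) {
  for (i in seq_along(swarm$particles)) {
    p <- swarm$particles[[i]]
    f <- fitness_fn(p$position)
    if (!is.finite(f) || f < 0 || f > 1)
      stop_psodt("fitness must be a number in [0, 1]; got ", f)
    if (is.na(p$pbest_fitness) || f > p$pbest_fitness) {
      p$pbest_fitness <- f
      p$pbest_position <- p$position
    }
    if (f > swarm$gbest_fitness) {
      swarm$gbest_fitness <- f
      swarm$gbest_position <- p$position
    }
    swarm$particles[[i]] <- p
  }
  for (i in seq_along(swarm$particles)) {
    p <- swarm$particles[[i]]
    p$velocity <- update_velocity(p, swarm$gbest_position, params, runif_fn)
    p$position <- update_position(p, runif_fn)
    swarm$particles[[i]] <- p
  }
  swarm$iteration <- swarm$iteration + 1L
  swarm$history <- c(swarm$history, swarm$gbest_fitness)
  swarm
}

#' Run the binary PSO to termination
#'
#' Repeats [pso_step()] until the global best fitness reaches
#' `target_fitness` or `max_iter` iterations have run.
#'
#' @param fitness_fn `function(position) -> fitness in [0, 1]`.
#' @param n_genes dimensionality.
#' @param params a [pso_params].
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @param runif_fn uniform generator.
#' @return list with `position` (best bit vector), `fitness`, `history`
#'   (global best per iteration) and `iterations` (number executed).
#' @examples
#' target <- c(1, 0, 1, 1, 0, 0, 1, 0)
#' fit <- function(x) mean(x == target)
#' res <- pso_run(fit, 8, pso_params(n_particles = 10, max_iter = 50), seed = 1)
#' res$fitness
#' @export
pso_run <- function(fitness_fn, n_genes, params = pso_params(), seed = NULL,
                    runif_fn = stats::runif) {
  with_seed(seed, {
    swarm <- init_swarm(n_genes, params, runif_fn)
    for (t in seq_len(params$max_iter)) {
      swarm <- pso_step(swarm, fitness_fn, params, runif_fn)
      if (swarm$gbest_fitness >= params$target_fitness) break
    }
    list(position = swarm$gbest_position, fitness = swarm$gbest_fitness,
         history = swarm$history, iterations = swarm$iteration)
  })
}
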