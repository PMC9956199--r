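#' Whale optimization configuration
#'
#' Settings for the whale optimization algorithm over a bounded box.
#' Minimization is the internal convention; negate a fitness to maximise.
#'
#' @param dim Problem dimension.
#' @param lower,upper Box bounds, scalars or per-dimension vectors.
#' @param population_size Number of whales; default 20.
#' @param iterations Iteration budget; default 100.
#' @param spiral_constant Shape constant of the logarithmic spiral;
#'   default 1.
#' @param seed Integer seed.
#' @return A `woa_config`.
#' @export
woa_config <- function(dim, lower = -1, upper = 1, population_size = 20L,
                       iterations = 100L, spiral_constant = 1, seed = 1L) {
  if (!is_count(dim)) stopf("dim must be a positive integer")
  if (!is_count(population_size) || population_size < 2L)
    stopf("population_size must be an integer >= 2")
  if (!is_count(iterations)) stopf("iterations must be an integer >= 1")
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (any(lower >= upper)) stopf("lower bounds must be below upper bounds")
  structure(list(dim = as.integer(dim), lower = lower, upper = upper,
                 population_size = as.integer(population_size),
                 iterations = as.integer(iterations),
                 spiral_constant = spiral_constant,
                 seed = as.integer(seed)),
            class = "woa_config")
}

#' Linearly decaying control coefficient
#'
#' The scalar `f` starts at 2 and decays linearly to 0 over the run:
#' `f = 2 (1 - k / (K - 1))` for 0-based iteration `k` of `K`. It drives
#' both the magnitude of the attack coefficient and the switch from
#' exploration to exploitation.
#'
#' @param k 0-based iteration index.
#' @param total Total number of iterations K.
#' @return The coefficient `f` in \[0, 2\].
#' @export
decay_coefficient <- function(k, total) {
  if (!is_count(total)) stopf("total iterations must be a positive integer")
  if (k < 0 || k >= total) stopf("iteration index %s out of [0, %d)", k, total)
  if (total == 1L) return(0)
  2 * (1 - k / (total - 1))
}

#' Random coefficient vectors of one whale move
#'
#' Draws `y ~ U(0,1)` per dimension from the current RNG stream and forms
#' `F = 2 f y - f` (each component in \[-f, f\]) and `R = 2 y` (in \[0, 2\]).
#'
#' @param f Current decay coefficient in \[0, 2\].
#' @param dim Dimension.
#' @param y Optional fixed draw (testing hook).
#' @return List with components `F_vec` and `R_vec`.
#' @export
coefficient_vectors <- function(f, dim, y = NULL) {
  if (is.null(y)) y <- runif(dim)
  list(F_vec = 2 * f * y - f, R_vec = 2 * y)
}

#' @noRd
clip_box <- function(x, lower, upper) pmin(pmax(x, lower), upper)

#' Whale position updates
#'
#' `encircle_update` shrinks toward the best whale:
#' `S = |R * G_best - G|`, `G' = G_best - F * S` (componentwise).
#' `spiral_update` moves along a logarithmic spiral around the best whale:
#' `G' = |G_best - G| e^{d s} cos(2 pi s) + G_best` with `s ~ U(-1, 1)`.
#' `explore_update` applies the encircling move toward a random whale
#' instead of the best. All results are clipped to the box.
#'
#' @param g Current position.
#' @param g_star Best position found so far.
#' @param f_vec,r_vec Coefficient vectors from [coefficient_vectors()].
#' @param lower,upper Box bounds.
#' @return The updated position.
#' @export
encircle_update <- function(g, g_star, f_vec, r_vec, lower, upper) {
  s <- abs(r_vec * g_star - g)
  clip_box(g_star - f_vec * s, lower, upper)
}

#' @rdname encircle_update
#' @param d Spiral shape constant.
#' @param s Spiral parameter in \[-1, 1\].
#' @export
spiral_update <- function(g, g_star, d, s, lower, upper) {
  r <- abs(g_star - g)
  clip_box(r * exp(d * s) * cos(2 * pi * s) + g_star, lower, upper)
}

#' @rdname encircle_update
#' @param g_rand Position of a randomly chosen whale.
#' @export
explore_update <- function(g, g_rand, f_vec, r_vec, lower, upper) {
  s <- abs(r_vec * g_rand - g)
  clip_box(g_rand - f_vec * s, lower, upper)
}

#' One iteration of whale optimization
#'
#' For every whale: with probability 1/2 take the spiral (bubble-net) move;
#' otherwise encircle the best whale when `max |F| < 1`, or a random other
#' whale (exploration) when `max |F| >= 1`. A draw of exactly p = 0.5 takes
#' the spiral branch. Fitness is re-evaluated and the incumbent best is
#' replaced only by a strictly better candidate (elitism).
#'
#' @param positions Matrix of whale positions (rows).
#' @param fitnesses Vector of current fitness values.
#' @param g_star,star_fit Incumbent best position and fitness.
#' @param k 0-based iteration index.
#' @param config A [woa_config()].
#' @param fitness_fn Function position -> scalar fitness (minimised).
#' @return List with updated `positions`, `fitnesses`, `g_star`, `star_fit`.
#' @export
woa_step <- function(positions, fitnesses, g_star, star_fit, k, config,
                     fitness_fn) {
  f <- decay_coefficient(k, config$iterations)
  n <- nrow(positions)
  for (i in seq_len(n)) {
    p <- runif(1)
    if (p >= 0.5) {
      s <- runif(1, -1, 1)
      cand <- spiral_update(positions[i, ], g_star, config$spiral_constant,
                            s, config$lower, config$upper)
    } else {
      cv <- coefficient_vectors(f, config$dim)
      if (max(abs(cv$F_vec)) >= 1) {
        others <- setdiff(seq_len(n), i)
        j <- if (length(others)) others[sample.int(length(others), 1L)] else i
        cand <- explore_update(positions[i, ], positions[j, ], cv$F_vec,
                               cv$R_vec, config$lower, config$upper)
      } else {
        cand <- encircle_update(positions[i, ], g_star, cv$F_vec, cv$R_vec,
                                config$lower, config$upper)
      }
    }
    fit <- fitness_fn(cand)
    if (!is.finite(fit))
      stopf("fitness function returned a non-finite value for whale %d", i)
    positions[i, ] <- cand
    fitnesses[i] <- fit
    if (fit < star_fit) {
      star_fit <- fit
      g_star <- cand
    }
  }
  list(positions = positions, fitnesses = fitnesses, g_star = g_star,
       star_fit = star_fit)
}

#' Run whale optimization
#'
#' Initialises the population uniformly in the box under the config seed,
#' runs the iteration budget, and returns the elitist best with the
#' per-iteration best-fitness history.
#'
#' @param fitness_fn Function position -> scalar fitness (minimised).
#' @param config A [woa_config()].
#' @param history_path Optional path for a line-delimited JSON trace
#'   (iteration, best fitness, decay coefficient).
#' @return List with `best_position`, `best_fitness`, and `history`
#'   (`data.frame` of `iteration`, `best_fitness`, `f`).
#' @export
#' @examples
#' cfg <- woa_config(dim = 1, lower = -5, upper = 5, iterations = 30,
#'                   seed = 7)
#' res <- woa_optimize(function(x) (x - 2)^2, cfg)
#' abs(res$best_position - 2) < 0.5
woa_optimize <- function(fitness_fn, config, history_path = NULL) {
  stopifnot(inherits(config, "woa_config"))
  with_seed(config$seed, {
    positions <- matrix(runif(config$population_size * config$dim),
                        config$population_size, config$dim)
    positions <- sweep(sweep(positions, 2L, config$upper - config$lower, "*"),
                       2L, config$lower, "+")
    fitnesses <- apply(positions, 1, fitness_fn)
    if (any(!is.finite(fitnesses)))
      stopf("fitness function returned a non-finite value for whale %d",
            which(!is.finite(fitnesses))[1])
    best <- which.min(fitnesses)
    g_star <- positions[best, ]
    star_fit <- fitnesses[best]
    history <- data.frame(iteration = integer(0), best_fitness = numeric(0),
                          f = numeric(0))
    for (k in seq_len(config$iterations) - 1L) {
      st <- woa_step(positions, fitnesses, g_star, star_fit, k, config,
                     fitness_fn)
      positions <- st$positions; fitnesses <- st$fitnesses
      g_star <- st$g_star; star_fit <- st$star_fit
      history <- rbind(history,
                       data.frame(iteration = k, best_fitness = star_fit,
                                  f = decay_coefficient(k,
                                                        config$iterations)))
      if (!is.null(history_path))
        cat(jsonlite::toJSON(list(iteration = k, best_fitness = star_fit,
                                  f = decay_coefficient(k,
                                                        config$iterations)),
                             auto_unbox = TRUE, digits = NA),
            "\n", sep = "", file = history_path, append = TRUE)
    }
  })
  list(best_position = g_star, best_fitness = star_fit, history = history)
}
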