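#' Contrast-adaptation environment
#'
#' The agent walks a discrete contrast grid: the state is the pair
#' (illumination bin, current contrast index) and the actions are
#' \{decrease `c` by one step, hold, increase\}. After each move the
#' environment returns the segmentation-quality reward of the new
#' contrast; an episode ends when the reward reaches `done_reward`
#' (optimal segmentation found) or the step cap is hit.
#'
#' @param reward_fn Function `(bin, c_value) -> reward in [0, 1]`.
#' @param n_bins Number of illumination bins (default 100, uniform over
#'   the configured operating range).
#' @param grid A [contrast_grid()].
#' @param illum_range Operating illumination range in lux covered by the
#'   bins (default `c(3500, 3600)`).
#' @param done_reward Reward at which an episode terminates (default
#'   0.99).
#' @return A list of class `contrast_env` with elements `n_bins`, `grid`,
#'   `n_states`, `n_actions`, `bin_edges`, and the closures
#'   `reset(bin)` and `step(state, action)`. States are lists
#'   `(illum_bin, c_index)`; `state_id()` maps them to Q-table rows.
#' @export
contrast_env <- function(reward_fn, n_bins = 100, grid = contrast_grid(),
                         illum_range = c(3500, 3600), done_reward = 0.99) {
  stopifnot(is.function(reward_fn), n_bins >= 1,
            inherits(grid, "contrast_grid"),
            length(illum_range) == 2, illum_range[1] < illum_range[2])
  n_c <- length(grid)
  env <- list(
    n_bins = as.integer(n_bins),
    grid = grid,
    n_states = as.integer(n_bins * n_c),
    n_actions = 3L,
    bin_edges = seq(illum_range[1], illum_range[2], length.out = n_bins + 1),
    done_reward = done_reward,
    state_id = function(state) (state$illum_bin - 1L) * n_c + state$c_index,
    reset = function(bin = NULL) {
      if (is.null(bin)) bin <- sample.int(n_bins, 1)
      list(illum_bin = as.integer(bin), c_index = sample.int(n_c, 1))
    },
    step = function(state, action) {
      # actions: 1 = decrease c, 2 = hold, 3 = increase c
      ci <- state$c_index + c(-1L, 0L, 1L)[action]
      ci <- min(max(ci, 1L), n_c)
      s2 <- list(illum_bin = state$illum_bin, c_index = ci)
      r <- reward_fn(state$illum_bin, grid[ci])
      list(state = s2, reward = r, done = r >= done_reward)
    })
  class(env) <- "contrast_env"
  env
}

#' Contrast environment backed by synthetic scenes
#'
#' Builds a [contrast_env()] whose reward is measured on rendered scenes:
#' for illumination bin `b`, the candidate segmentation is the Otsu
#' foreground of the contrast-adjusted scene image and its mismatch
#' spacing against the scene's ground-truth mask is compared to the best
#' (standard) spacing found on a coarse contrast sweep of a calibration
#' scene.
#'
#' @param scenes List of `synthetic_scene`s, one per illumination bin
#'   (e.g. from [generate_illumination_series()]).
#' @param grid A [contrast_grid()].
#' @param illum_range Operating range in lux (defaults to the range of the
#'   scene illuminations).
#' @param calibration_sweep Contrast values swept to determine the
#'   standard spacing (default every 0.05).
#' @param ... Passed to [contrast_env()].
#' @return A `contrast_env`.
#' @export
contrast_env_from_scenes <- function(scenes, grid = contrast_grid(),
                                     illum_range = NULL,
                                     calibration_sweep = seq(0, 1, by = 0.05),
                                     ...) {
  stopifnot(length(scenes) >= 1,
            all(vapply(scenes, inherits, logical(1), "synthetic_scene")))
  n_bins <- length(scenes)
  if (is.null(illum_range)) {
    il <- vapply(scenes, function(s) s$image$illumination, numeric(1))
    illum_range <- if (n_bins > 1) range(il) else il[1] + c(-0.5, 0.5)
  }
  truths <- lapply(scenes, truth_mask)
  grays <- lapply(scenes, function(s) preprocess(s$image))
  spacing_of <- function(bin, cv) {
    cand <- suppressWarnings(otsu_binarize(apply_contrast(grays[[bin]], cv)))
    mismatch_spacing(cand, truths[[bin]])
  }
  standard <- vapply(seq_len(n_bins), function(b) {
    min(vapply(calibration_sweep, function(cv) spacing_of(b, cv), numeric(1)))
  }, numeric(1))
  memo <- lapply(seq_len(n_bins), function(b)
    rep(NA_real_, length(unclass(grid))))
  memo_env <- new.env(parent = emptyenv())
  assign("memo", memo, envir = memo_env)
  reward_fn <- function(bin, c_value) {
    ci <- which.min(abs(unclass(grid) - c_value))
    m <- get("memo", envir = memo_env)
    if (is.na(m[[bin]][ci])) {
      m[[bin]][ci] <- reward_spacing(spacing_of(bin, c_value), standard[bin])
      assign("memo", m, envir = memo_env)
    }
    m[[bin]][ci]
  }
  contrast_env(reward_fn, n_bins = n_bins, grid = grid,
               illum_range = illum_range, ...)
}

#' Train the contrast-adaptation policy with Sarsa
#'
#' Runs episodic on-policy Sarsa on a [contrast_env()]: each episode
#' starts at a random contrast in a (cycled) illumination bin, actions are
#' chosen epsilon-greedily with a decaying epsilon, and Q is updated from
#' the quintuple `(s, a, r, s', a')`. The learned policy maps each
#' illumination bin to a contrast value: the rollout of the greedy policy
#' started from the bin's highest-valued state.
#'
#' @param env A [contrast_env()].
#' @param cfg A [sarsa_config()].
#' @return A list of class `contrast_policy`: `policy` (contrast value per
#'   bin), `q` (Q matrix), `trace` (per-episode data frame: episode, bin,
#'   epsilon, steps, final reward, final contrast, max Q), `bin_edges`,
#'   `grid` and `cfg`.
#' @export
train_contrast_policy <- function(env, cfg = sarsa_config()) {
  stopifnot(inherits(env, "contrast_env"), inherits(cfg, "sarsa_config"))
  with_seed(cfg$seed, {
    q <- matrix(0, env$n_states, env$n_actions)
    n_ep <- cfg$episodes
    trace <- data.frame(episode = seq_len(n_ep), bin = NA_integer_,
                        epsilon = NA_real_, steps = NA_integer_,
                        reward = NA_real_, c_final = NA_real_,
                        q_max = NA_real_)
    eps <- cfg$epsilon_start
    for (ep in seq_len(n_ep)) {
      bin <- (ep - 1L) %% env$n_bins + 1L
      s <- env$reset(bin)
      a <- epsilon_greedy(q, env$state_id(s), eps)
      steps <- 0L
      r <- NA_real_
      repeat {
        steps <- steps + 1L
        out <- env$step(s, a)
        r <- out$reward
        done <- out$done || steps >= cfg$step_cap
        a2 <- epsilon_greedy(q, env$state_id(out$state), eps)
        if (out$done && cfg$gamma < 1) {
          # the optimum is absorbing: reaching it is worth its sustained
          # reward, r + gamma r + gamma^2 r + ... = r / (1 - gamma)
          q <- sarsa_update(q, env$state_id(s), a, r / (1 - cfg$gamma),
                            env$state_id(out$state), a2, cfg,
                            terminal = TRUE)
        } else {
          q <- sarsa_update(q, env$state_id(s), a, r,
                            env$state_id(out$state), a2, cfg,
                            terminal = out$done)
        }
        s <- out$state
        a <- a2
        if (done) break
      }
      trace$bin[ep] <- bin
      trace$epsilon[ep] <- eps
      trace$steps[ep] <- steps
      trace$reward[ep] <- r
      trace$c_final[ep] <- env$grid[s$c_index]
      trace$q_max[ep] <- max(q)
      eps <- max(cfg$epsilon_end, eps * cfg$epsilon_decay)
    }
    policy <- vapply(seq_len(env$n_bins), function(bin)
      greedy_rollout(env, q, bin, cfg$step_cap), numeric(1))
    structure(list(policy = policy, q = q, trace = trace,
                   bin_edges = env$bin_edges, grid = env$grid, cfg = cfg),
              class = "contrast_policy")
  })
}

# deterministic greedy descent to the terminal contrast of one bin
greedy_rollout <- function(env, q, bin, step_cap) {
  n_c <- length(env$grid)
  ids <- (bin - 1L) * n_c + seq_len(n_c)
  ci <- which.max(apply(q[ids, , drop = FALSE], 1, max))
  s <- list(illum_bin = as.integer(bin), c_index = as.integer(ci))
  for (k in seq_len(step_cap)) {
    a <- which.max(q[env$state_id(s), ])
    out <- env$step(s, a)
    s <- out$state
    if (out$done) break
  }
  env$grid[s$c_index]
}

#' @export
print.contrast_policy <- function(x, ...) {
  cat(sprintf("contrast_policy: %d illumination bins over [%.4g, %.4g] Lx\n",
              length(x$policy), min(x$bin_edges), max(x$bin_edges)))
  cat(sprintf("  learned c: %s\n",
              paste(sprintf("%.2f", range(x$policy)), collapse = " - ")))
  cat(sprintf("  episodes: %d, final max Q: %.3f\n",
              x$cfg$episodes, x$trace$q_max[nrow(x$trace)]))
  invisible(x)
}

#' Look up the contrast for an illumination
#'
#' @param object A `contrast_policy` from [train_contrast_policy()].
#' @param illumination Illumination values in lux.
#' @param ... Unused.
#' @return The learned contrast values (edges are clamped to the operating
#'   range).
#' @export
predict.contrast_policy <- function(object, illumination, ...) {
  bins <- findInterval(illumination, object$bin_edges,
                       rightmost.closed = TRUE)
  bins <- pmin(pmax(bins, 1L), length(object$policy))
  object$policy[bins]
}

#' @export
plot.contrast_policy <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$trace$episode, x$trace$q_max, type = "l",
                 xlab = "episode", ylab = "max Q", main = "Q learning curve")
  graphics::plot(x$trace$episode, x$trace$c_final, type = "p", pch = 16,
                 cex = 0.4, xlab = "episode", ylab = "episode-final c",
                 main = "contrast parameter")
  invisible(x)
}
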