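#' Sarsa training configuration
#'
#' On-policy temporal-difference control with an epsilon-greedy behaviour
#' policy. The learning rate and discount defaults (alpha 0.1, gamma 0.9)
#' balance convergence speed against stability; exploration decays
#' exponentially from `epsilon_start` to `epsilon_end` over the episodes.
#'
#' @param alpha Learning rate in `[0, 1]` (default 0.1).
#' @param gamma Discount factor in `(0, 1]` (default 0.9).
#' @param epsilon_start,epsilon_end Exploration schedule ends (defaults
#'   0.9 and 0.05).
#' @param epsilon_decay Per-episode multiplicative decay; when `NULL`
#'   (default) it is derived so that `epsilon_end` is reached on the final
#'   episode.
#' @param episodes Number of training episodes (default 500).
#' @param step_cap Maximum environment steps per episode (default 200).
#' @param seed RNG seed for reproducible training, or `NULL`.
#' @return A list of class `sarsa_config`.
#' @export
sarsa_config <- function(alpha = 0.1, gamma = 0.9,
                         epsilon_start = 0.9, epsilon_end = 0.05,
                         epsilon_decay = NULL, episodes = 500,
                         step_cap = 200, seed = NULL) {
  stopifnot(alpha >= 0, alpha <= 1, gamma > 0, gamma <= 1,
            epsilon_start >= 0, epsilon_start <= 1,
            epsilon_end >= 0, epsilon_end <= epsilon_start,
            episodes >= 1, step_cap >= 1)
  if (is.null(epsilon_decay)) {
    epsilon_decay <- if (episodes > 1 && epsilon_start > 0 && epsilon_end > 0)
      (epsilon_end / epsilon_start)^(1 / (episodes - 1)) else 1
  }
  structure(list(alpha = alpha, gamma = gamma,
                 epsilon_start = epsilon_start, epsilon_end = epsilon_end,
                 epsilon_decay = epsilon_decay, episodes = as.integer(episodes),
                 step_cap = as.integer(step_cap), seed = seed),
            class = "sarsa_config")
}

#' Discrete contrast-parameter grid
#'
#' The contrast-adjustment parameter `c` is quantized on a uniform grid in
#' `[0, 1]` (default step 0.01, i.e. 101 levels).
#'
#' @param step Grid step in `(0, 1]`.
#' @return Numeric vector of class `contrast_grid`, strictly increasing in
#'   `[0, 1]`.
#' @export
contrast_grid <- function(step = 0.01) {
  stopifnot(step > 0, step <= 1)
  structure(seq(0, 1, by = step), class = "contrast_grid")
}

#' One Sarsa update
#'
#' `Q(s, a) <- Q(s, a) + alpha * (r + gamma * Q(s', a') - Q(s, a))`.
#' On-policy: the bootstrap uses the action actually taken next (`a_next`),
#' not the greedy maximum.
#'
#' @param q Numeric Q matrix (states x actions).
#' @param s,a Current state and action indices.
#' @param r Finite reward.
#' @param s_next,a_next Next state and action indices (ignored when
#'   `terminal`).
#' @param cfg A [sarsa_config()].
#' @param terminal Whether the transition ends the episode (the bootstrap
#'   term is dropped).
#' @return The updated Q matrix (exactly one entry changes).
#' @export
sarsa_update <- function(q, s, a, r, s_next, a_next, cfg = sarsa_config(),
                         terminal = FALSE) {
  stopifnot(is.matrix(q), is.finite(r))
  target <- r + if (terminal) 0 else cfg$gamma * q[s_next, a_next]
  q[s, a] <- q[s, a] + cfg$alpha * (target - q[s, a])
  q
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon` a uniformly random action; otherwise the
#' greedy action, ties broken deterministically toward the lowest index.
#'
#' @param q Numeric Q matrix (states x actions) with at least one action.
#' @param s State row index.
#' @param epsilon Exploration probability in `[0, 1]`.
#' @return An action column index.
#' @export
epsilon_greedy <- function(q, s, epsilon) {
  stopifnot(is.matrix(q), ncol(q) >= 1, epsilon >= 0, epsilon <= 1)
  if (epsilon > 0 && runif(1) < epsilon) sample.int(ncol(q), 1)
  else which.max(q[s, ])
}

#' Affine contrast adjustment
#'
#' Stretches a grayscale raster about its mean:
#' `out = clip(mu + (1 + s_gain * c) * (x - mu), 0, 1)`. `c = 0` is the
#' identity; `c = 1` triples the deviation from the mean at the default
#' gain of 2.
#'
#' @param image Grayscale matrix in `[0, 1]`.
#' @param c Contrast parameter in `[0, 1]`.
#' @param s_gain Slope gain mapping `c` to the stretch factor (default 2).
#' @return The adjusted raster.
#' @export
apply_contrast <- function(image, c, s_gain = 2) {
  x <- as_gray_matrix(image)
  if (!is.numeric(c) || length(c) != 1L || c < 0 || c > 1)
    stop("contrast parameter c must be a single value in [0, 1]")
  mu <- mean(x)
  pmin(pmax(mu + (1 + s_gain * c) * (x - mu), 0), 1)
}

#' Average spacing of mismatched pixels
#'
#' Segmentation-quality metric: over the pixels where `candidate` and
#' `reference` disagree (XOR), the mean Euclidean distance to the nearest
#' boundary pixel of the reference foreground. Identical masks score 0;
#' large or badly placed mismatches score high.
#'
#' @param candidate,reference Logical masks of identical shape; the
#'   reference must contain at least one foreground pixel.
#' @return Mean spacing in pixels (>= 0).
#' @export
mismatch_spacing <- function(candidate, reference) {
  cand <- as_gray_matrix(candidate) != 0
  ref <- as_gray_matrix(reference) != 0
  check_same_shape(cand, ref, c("candidate", "reference"))
  if (!any(ref)) stop("reference mask must be non-empty")
  mism <- xor(cand, ref)
  if (!any(mism)) return(0)
  nr <- nrow(ref); nc <- ncol(ref)
  # boundary: reference foreground pixels 4-adjacent to background
  # (the image edge counts as background)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- ref
  inner <- pad[2:(nr + 1), 2:(nc + 1)] &
    !(pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
        pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)])
  boundary <- ref & inner
  dist <- EBImage::imageData(EBImage::distmap(EBImage::Image(1 - boundary)))
  mean(dist[mism])
}

#' Spacing-based reward
#'
#' Ratio of the standard (best achievable) spacing to the real-time
#' spacing, clipped to `[0, 1]` so the optimum scores 1:
#' `r = min(standard / realtime, 1)`; both spacings 0 also score 1.
#'
#' @param realtime_spacing Spacing of the candidate segmentation (pixels).
#' @param standard_spacing Spacing of the reference (best) segmentation.
#' @return Reward in `[0, 1]`; higher is better.
#' @export
reward_spacing <- function(realtime_spacing, standard_spacing) {
  stopifnot(is.numeric(realtime_spacing), is.numeric(standard_spacing))
  if (any(realtime_spacing < 0) || any(standard_spacing < 0))
    stop("spacings must be non-negative")
  ifelse(standard_spacing == 0,
         as.numeric(realtime_spacing == 0),
         pmin(standard_spacing / pmax(realtime_spacing, .EPS_NUM), 1))
}
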