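#' Arcade-game configuration
#'
#' Builds the configuration block for the bundled arcade game that serves as
#' the generative process for de novo learning.  The game is played on a
#' 12 x 9 pixel grid (row 1 is the top row, the paddle slides along the
#' bottom row).  A ball bounces between the paddle and rows of targets at the
#' top of the box; hitting any target removes the entire front row, and only
#' hits on the central columns are rewarded.  Missing the ball, or letting a
#' bomb land on the paddle, is punished.  All engine parameters are exposed
#' here; the defaults define the study conditions used throughout the
#' package, calibrated so that a perfect rally cycle yields the published
#' pace of play (11 rewards per 200 frames).
#'
#' @param n_cols,n_rows grid size in columns and rows (108 pixels).
#' @param n_target_rows number of target rows stacked from the top.
#' @param central_cols columns whose targets elicit a reward when struck.
#' @param spawn_col,spawn_row spawn cell of the ball after a full reset
#'   (descending vertically).
#' @param miss_cols the three columns from which the ball respawns, chosen
#'   uniformly at random, after a miss.
#' @param paddle_halfwidth the paddle covers \code{2*halfwidth + 1} cells
#'   centred on its reported column.
#' @param bomb_cols fixed distinct columns at which three bombs appear when
#'   the paddle returns the ball.
#' @param bomb_trigger_cols bombs are released whenever the paddle returns
#'   the ball at one of these columns (a deterministic function of the
#'   visible state, so the engine has no hidden clock).
#' @param bomb_spawn_row row at which bombs appear (four rows above the
#'   paddle); bombs descend one row per frame.
#' @param seed integer seed for the game's own random stream (miss respawns).
#' @return a list of class \code{"game_config"}.
#' @export
game_config <- function(n_cols = 12L, n_rows = 9L, n_target_rows = 2L,
                        central_cols = c(6L, 7L),
                        spawn_col = 6L, spawn_row = 5L,
                        miss_cols = c(4L, 7L, 10L),
                        paddle_halfwidth = 2L,
                        bomb_cols = c(2L, 10L, 11L),
                        bomb_trigger_cols = c(2L, 10L),
                        bomb_spawn_row = 5L,
                        seed = 1L) {
  stopifnot(n_cols >= 4L, n_rows >= 5L,
            n_target_rows >= 1L, n_target_rows < spawn_row,
            all(central_cols >= 1L & central_cols <= n_cols),
            spawn_row < n_rows - 1L,
            all(miss_cols >= 1L & miss_cols <= n_cols),
            paddle_halfwidth >= 0L,
            all(bomb_cols >= 1L & bomb_cols <= n_cols),
            bomb_spawn_row < n_rows)
  cfg <- list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
              n_target_rows = as.integer(n_target_rows),
              central_cols = as.integer(central_cols),
              spawn_col = as.integer(spawn_col), spawn_row = as.integer(spawn_row),
              miss_cols = as.integer(miss_cols),
              paddle_halfwidth = as.integer(paddle_halfwidth),
              bomb_cols = as.integer(bomb_cols),
              bomb_trigger_cols = as.integer(bomb_trigger_cols),
              bomb_spawn_row = as.integer(bomb_spawn_row),
              paddle_row = as.integer(n_rows),
              seed = as.integer(seed))
  class(cfg) <- "game_config"
  cfg
}

#' Observation layout of the game
#'
#' The game emits 111 one-hot observation channels per frame: one 5-symbol
#' channel per pixel (empty, target, ball, paddle, bomb), a binary reward
#' channel, a binary punishment channel, and a 12-valued proprioceptive
#' channel reporting the paddle column.
#'
#' @param cfg a \code{\link{game_config}}.
#' @return list with \code{n_channels}, per-channel alphabet \code{sizes},
#'   and \code{streams} labels (\code{pixel}, \code{reward},
#'   \code{punishment}, \code{proprio}).
#' @export
obs_layout <- function(cfg = game_config()) {
  npx <- cfg$n_cols * cfg$n_rows
  list(n_channels = npx + 3L,
       sizes = c(rep(5L, npx), 2L, 2L, cfg$n_cols),
       streams = c(rep("pixel", npx), "reward", "punishment", "proprio"))
}

## Lehmer multiplicative congruential generator: the game owns its random
## stream so replays are bit-for-bit reproducible independently of R's RNG.
.lcg_seed <- function(seed) {
  s <- as.double(seed %% 2147483646L)
  if (s <= 0) s <- s + 2147483645
  s
}
.lcg_next <- function(s) (s * 48271) %% 2147483647
.lcg_pick <- function(s, k) {
  s <- .lcg_next(s)
  list(state = s, draw = as.integer(s %% k) + 1L)
}

.full_reset <- function(st) {
  cfg <- st$cfg
  st$rows_remaining <- cfg$n_target_rows
  st$ball_col <- cfg$spawn_col
  st$ball_row <- cfg$spawn_row
  st$ball_vx <- 0L
  st$ball_vy <- 1L
  st$paddle_col <- cfg$spawn_col   # a fresh board re-centres the paddle
  st$paddle_vel <- 0L
  st$bombs <- matrix(integer(0), 0L, 2L)
  st$rearm_pending <- FALSE
  st
}

.miss_reset <- function(st, miss_col = NULL) {
  cfg <- st$cfg
  if (is.null(miss_col)) {
    p <- .lcg_pick(st$rng, length(cfg$miss_cols))
    st$rng <- p$state
    miss_col <- cfg$miss_cols[p$draw]
  }
  st$ball_col <- as.integer(miss_col)
  st$ball_row <- cfg$spawn_row
  st$ball_vx <- 0L
  st$ball_vy <- 1L
  st
}

#' Start a fresh game
#'
#' @param cfg a \code{\link{game_config}}.
#' @param seed optional override of \code{cfg$seed} for the game's random
#'   stream.
#' @return a \code{"game_state"}: ball and paddle positions and velocities,
#'   remaining target rows, bombs in flight, frame counter and the opaque
#'   random-stream state.
#' @export
new_game <- function(cfg = game_config(), seed = NULL) {
  st <- list(cfg = cfg,
             paddle_col = cfg$spawn_col, paddle_vel = 0L,
             frame = 0L,
             rng = .lcg_seed(if (is.null(seed)) cfg$seed else seed))
  st <- .full_reset(st)
  class(st) <- "game_state"
  st
}

#' Reset a game state
#'
#' A \code{full} reset restores every target row and places the ball at the
#' central spawn cell, descending; a \code{miss} reset keeps the targets and
#' respawns the ball at one of three fixed columns chosen at random (same
#' height, descending).
#'
#' @param state a \code{"game_state"}.
#' @param mode \code{"full"} or \code{"miss"}.
#' @param miss_col optionally force the respawn column (used for exhaustive
#'   enumeration of the stochastic branch).
#' @return the reset \code{"game_state"}.
#' @export
game_reset <- function(state, mode = c("full", "miss"), miss_col = NULL) {
  mode <- match.arg(mode)
  if (mode == "full") .full_reset(state) else .miss_reset(state, miss_col)
}

.observe <- function(st, rewarded, punished) {
  cfg <- st$cfg
  nc <- cfg$n_cols
  px <- rep(1L, nc * cfg$n_rows)
  if (st$rows_remaining > 0L) px[seq_len(st$rows_remaining * nc)] <- 2L
  if (nrow(st$bombs)) px[(st$bombs[, 2L] - 1L) * nc + st$bombs[, 1L]] <- 5L
  pcells <- (st$paddle_col - cfg$paddle_halfwidth):(st$paddle_col + cfg$paddle_halfwidth)
  pcells <- pcells[pcells >= 1L & pcells <= nc]
  px[(cfg$paddle_row - 1L) * nc + pcells] <- 4L
  px[(st$ball_row - 1L) * nc + st$ball_col] <- 3L
  c(px, 1L + rewarded, 1L + punished, st$paddle_col)
}

#' Advance the game by one frame
#'
#' Moves the paddle (clamped at the walls, and remembering the executed move
#' as the paddle's velocity), then the ball by one cell per velocity
#' component, reflecting off the side walls.  A ball moving up into the front
#' target row removes that whole row, with a reward if and only if the struck
#' column is central; the ball is returned downward.  A descending ball
#' reaching the row above the paddle, with the paddle beneath it, bounces
#' back up and inherits the paddle's velocity as its horizontal velocity
#' (the paddle is sticky).  A ball passing the paddle row unintercepted is a
#' loss and triggers a miss reset.  Each paddle return releases three bombs
#' at fixed columns four rows above the paddle; a bomb landing on the paddle
#' is a loss unless the ball sits directly above the paddle at that column.
#' After the last target row is cleared, the board re-arms when the ball next
#' reaches the top row, and the full reset executes on the following frame.
#'
#' @param state a \code{"game_state"}.
#' @param action \code{1} (left), \code{2} (stay) or \code{3} (right); the
#'   strings \code{"left"}, \code{"stay"}, \code{"right"} are also accepted.
#' @param miss_col see \code{\link{game_reset}}.
#' @return list with the new \code{state}, the 111-channel integer symbol
#'   vector \code{obs}, and logical flags \code{rewarded} and \code{lost}.
#' @export
game_step <- function(state, action, miss_col = NULL) {
  if (is.character(action))
    action <- match(action, c("left", "stay", "right"))
  if (is.na(action) || length(action) != 1L || !(action %in% 1:3))
    stop("invalid action: must be 1 (left), 2 (stay) or 3 (right)")
  cfg <- state$cfg
  st <- state
  st$frame <- st$frame + 1L
  rewarded <- FALSE
  lost_ball <- FALSE
  lost_bomb <- FALSE
  volley <- FALSE

  newp <- min(max(st$paddle_col + (action - 2L), 1L), cfg$n_cols)
  st$paddle_vel <- newp - st$paddle_col
  st$paddle_col <- newp

  if (st$rearm_pending) {
    st <- .full_reset(st)
  } else {
    vx <- st$ball_vx
    vy <- st$ball_vy
    ncol_ <- st$ball_col + vx
    if (ncol_ < 1L) { vx <- 1L; ncol_ <- st$ball_col + 1L }
    else if (ncol_ > cfg$n_cols) { vx <- -1L; ncol_ <- st$ball_col - 1L }
    nrow_ <- st$ball_row + vy
    if (vy < 0L && st$rows_remaining > 0L && nrow_ == st$rows_remaining) {
      ## front-row strike: whole row disappears
      st$rows_remaining <- st$rows_remaining - 1L
      rewarded <- ncol_ %in% cfg$central_cols
      vy <- 1L
    } else if (vy < 0L && nrow_ <= 1L) {
      if (nrow_ < 1L) { vy <- 1L; nrow_ <- st$ball_row + 1L }  # top wall
      else if (st$rows_remaining == 0L) st$rearm_pending <- TRUE
    } else if (vy > 0L && nrow_ == cfg$paddle_row - 1L &&
               abs(ncol_ - st$paddle_col) <= cfg$paddle_halfwidth) {
      vy <- -1L
      vx <- st$paddle_vel   # sticky paddle confers its momentum
      volley <- ncol_ %in% cfg$bomb_trigger_cols
    } else if (vy > 0L && nrow_ >= cfg$paddle_row) {
      lost_ball <- TRUE
    }
    if (lost_ball) {
      st <- .miss_reset(st, miss_col)
    } else {
      st$ball_col <- ncol_
      st$ball_row <- nrow_
      st$ball_vx <- vx
      st$ball_vy <- vy
    }
  }

  if (nrow(st$bombs)) {
    st$bombs[, 2L] <- st$bombs[, 2L] + 1L
    landing <- st$bombs[, 2L] >= cfg$paddle_row
    if (any(landing)) {
      for (b in st$bombs[landing, 1L]) {
        shielded <- st$ball_col == b && st$ball_row >= cfg$paddle_row - 1L
        if (abs(b - st$paddle_col) <= cfg$paddle_halfwidth && !shielded)
          lost_bomb <- TRUE
      }
      st$bombs <- st$bombs[!landing, , drop = FALSE]
    }
  }
  if (volley && length(cfg$bomb_cols))
    st$bombs <- rbind(st$bombs,
                      cbind(cfg$bomb_cols, rep(cfg$bomb_spawn_row, length(cfg$bomb_cols))))

  lost <- lost_ball || lost_bomb
  list(state = st,
       obs = .observe(st, rewarded, lost),
       rewarded = rewarded,
       lost = lost)
}

#' Play a sequence of frames
#'
#' Drives the game for \code{n} frames under a policy and records the full
#' observation stream.
#'
#' @param state a \code{"game_state"} to start from.
#' @param n number of frames.
#' @param policy \code{"random"} (uniform over the three actions, drawn from
#'   the game's own random stream), \code{"stay"}, or a function
#'   \code{function(state, obs) -> action}.
#' @return list with \code{obs} (integer matrix, 111 x n), \code{actions},
#'   logical vectors \code{rewarded} and \code{lost}, and the final
#'   \code{state}.
#' @export
play_frames <- function(state, n, policy = "random") {
  lay <- obs_layout(state$cfg)
  obs <- matrix(0L, lay$n_channels, n)
  actions <- integer(n)
  rewarded <- logical(n)
  lost <- logical(n)
  st <- state
  prev <- .observe(st, FALSE, FALSE)
  for (i in seq_len(n)) {
    a <- if (is.function(policy)) {
      policy(st, prev)
    } else if (identical(policy, "stay")) {
      2L
    } else {
      p <- .lcg_pick(st$rng, 3L)
      st$rng <- p$state
      p$draw
    }
    stp <- game_step(st, a)
    st <- stp$state
    obs[, i] <- stp$obs
    actions[i] <- a
    rewarded[i] <- stp$rewarded
    lost[i] <- stp$lost
    prev <- stp$obs
  }
  list(obs = obs, actions = actions, rewarded = rewarded, lost = lost,
       state = st)
}

#' Render a game state as a character grid
#'
#' @param state a \code{"game_state"}.
#' @return character matrix (rows x columns) using \code{.} empty,
#'   \code{#} target, \code{o} ball, \code{=} paddle, \code{*} bomb;
#'   consistent with the pixel channels of the emitted observation.
#' @export
render_game <- function(state) {
  sym <- .observe(state, FALSE, FALSE)
  cfg <- state$cfg
  glyphs <- c(".", "#", "o", "=", "*")
  matrix(glyphs[sym[seq_len(cfg$n_cols * cfg$n_rows)]],
         cfg$n_rows, cfg$n_cols, byrow = TRUE)
}

#' @export
print.game_state <- function(x, ...) {
  g <- render_game(x)
  cat(apply(g, 1L, paste, collapse = ""), sep = "\n")
  cat(sprintf("frame %d | rows %d | ball (%d,%d) v(%d,%d) | paddle %d\n",
              x$frame, x$rows_remaining, x$ball_col, x$ball_row,
              x$ball_vx, x$ball_vy, x$paddle_col))
  invisible(x)
}

#' Expand an observation into one-hot channel vectors
#'
#' @param sym integer symbol vector as returned in \code{game_step()$obs}.
#' @param cfg a \code{\link{game_config}}.
#' @return list of 111 one-hot numeric vectors, one per channel.
#' @export
obs_onehot <- function(sym, cfg = game_config()) {
  lay <- obs_layout(cfg)
  lapply(seq_along(sym), function(i) {
    v <- numeric(lay$sizes[i])
    v[sym[i]] <- 1
    v
  })
}

.state_key <- function(st) {
  paste(st$ball_col, st$ball_row, st$ball_vx, st$ball_vy,
        st$paddle_col, st$paddle_vel, st$rows_remaining,
        as.integer(st$rearm_pending),
        paste(t(st$bombs), collapse = " "),
        sep = "|")
}

#' Enumerate reachable game states
#'
#' Breadth-first enumeration of the engine's reachable state set from the
#' initial state, branching over all three actions and (for miss resets) all
#' respawn columns, up to a depth limit.  Reports the analogous counts to the
#' engine-level state and transition tallies of the source system.
#'
#' @param cfg a \code{\link{game_config}}.
#' @param depth maximum number of frames explored from the start state.
#' @param max_states safety cap on the number of stored states.
#' @return list with \code{n_states}, \code{n_transitions} and the visited
#'   depth.
#' @export
enumerate_states <- function(cfg = game_config(), depth = 50L,
                             max_states = 200000L) {
  st0 <- new_game(cfg)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  assign(.state_key(st0), TRUE, envir = seen)
  frontier <- list(st0)
  n_trans <- 0L
  d <- 0L
  while (length(frontier) && d < depth) {
    d <- d + 1L
    nxt <- list()
    for (st in frontier) {
      for (a in 1:3) {
        ## branch the stochastic miss respawn explicitly
        branches <- lapply(cfg$miss_cols, function(mc) game_step(st, a, miss_col = mc)$state)
        keys <- vapply(branches, .state_key, "")
        ub <- !duplicated(keys)
        branches <- branches[ub]; keys <- keys[ub]
        n_trans <- n_trans + length(keys)
        for (j in seq_along(keys)) {
          if (!exists(keys[j], envir = seen, inherits = FALSE)) {
            assign(keys[j], TRUE, envir = seen)
            nxt[[length(nxt) + 1L]] <- branches[[j]]
          }
        }
      }
      if (length(seen) > max_states) stop("state cap exceeded")
    }
    frontier <- nxt
  }
  list(n_states = length(seen), n_transitions = n_trans, depth = d)
}
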