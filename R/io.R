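.ARCHIVE_VERSION <- "denovolearn-model-1"

.tab_dump <- function(tb) {
  out <- list()
  for (nm in ls(tb, all.names = TRUE)) {
    v <- get(nm, envir = tb)
    out[[nm]] <- if (is.environment(v)) .tab_dump(v) else v
  }
  out
}

.tab_load <- function(lst, nested = "tr") {
  e <- new.env(parent = emptyenv())
  for (nm in names(lst)) {
    v <- lst[[nm]]
    assign(nm, if (nm %in% nested && is.list(v)) .tab_load(v) else v, envir = e)
  }
  e
}

#' Save a model archive
#'
#' Writes a lossless plain-text (JSON) archive of a \code{denovo_model}: the
#' manifest records the archive version, configuration and dimensions, and
#' every count vector and dictionary is stored exactly.
#'
#' @param model a \code{denovo_model}.
#' @param path file path (conventionally \code{.json}).
#' @return \code{path}, invisibly.
#' @export
save_model <- function(model, path) {
  cfg <- unclass(model$config)
  cfg$game <- unclass(cfg$game)
  payload <- list(
    version = .ARCHIVE_VERSION,
    config = cfg,
    layout = model$layout,
    phase = model$phase,
    static = model$static, static_sym = model$static_sym,
    factors = lapply(model$factors, .tab_dump),
    top = if (is.null(model$top)) NULL else .tab_dump(model$top),
    history = model$history,
    attractor_converged = isTRUE(model$attractor_converged))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

.fix_int <- function(e, nms) {
  for (nm in nms) if (!is.null(e[[nm]])) e[[nm]] <- as.integer(e[[nm]])
  e
}

#' Load a model archive
#'
#' @param path a file written by \code{\link{save_model}}.
#' @return the reconstructed \code{denovo_model}; tensors round-trip exactly.
#' @export
load_model <- function(path) {
  p <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                    simplifyDataFrame = FALSE,
                                    simplifyMatrix = FALSE),
                error = function(e) stop("corrupt model archive: ",
                                         conditionMessage(e)))
  if (!identical(p$version, .ARCHIVE_VERSION))
    stop("model archive version mismatch: found ",
         if (is.null(p$version)) "<none>" else p$version)
  for (nm in c("layout", "factors"))
    if (is.null(p[[nm]])) stop("corrupt model archive: missing ", nm)
  cl <- p$config
  game <- do.call(game_config,
                  cl$game[names(cl$game) %in% names(formals(game_config))])
  rest <- cl[names(cl) %in% setdiff(names(formals(denovo_config)), "game")]
  cfg <- do.call(denovo_config, c(list(game = game), rest))
  m <- .model_new(cfg, p$layout)
  m$phase <- p$phase
  m$static <- as.integer(p$static)
  m$static_sym <- as.integer(p$static_sym)
  m$factors <- lapply(p$factors, function(f) {
    e <- .tab_load(f)
    e <- .fix_int(e, c("channels", "outdeg"))
    e$tr <- .fix_int(e$tr, c("from", "to", "slot"))
    if (is.null(e$keys)) e$keys <- character(0)
    e
  })
  if (!is.null(p$top)) {
    t <- .tab_load(p$top)
    t <- .fix_int(t, c("outdeg", "n_states", "cause_factor", "id_map"))
    t$tr <- .fix_int(t$tr, c("from", "to", "slot"))
    t$active <- as.logical(t$active)
    t$goal <- as.logical(t$goal)
    t$cost <- as.logical(t$cost)
    if (is.null(t$keys)) t$keys <- character(0)
    m$top <- t
  }
  m$history <- p$history
  m$attractor_converged <- isTRUE(p$attractor_converged)
  m
}

#' Write an observation log as JSON lines
#'
#' One record per frame with the frame index, executed action, the 111
#' channel symbols, and the reward/loss flags.
#'
#' @param run a result of \code{\link{play_frames}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_frames_jsonl <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(ncol(run$obs))) {
    rec <- list(frame = i, action = run$actions[i],
                channels = run$obs[, i],
                rewarded = run$rewarded[i], lost = run$lost[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read an observation log written by \code{\link{write_frames_jsonl}}
#'
#' @param path JSONL file.
#' @return list with \code{obs} (channels x frames), \code{actions},
#'   \code{rewarded}, \code{lost}.
#' @export
read_frames_jsonl <- function(path) {
  recs <- lapply(readLines(path), jsonlite::fromJSON)
  list(obs = vapply(recs, function(r) as.integer(r$channels),
                    integer(length(recs[[1L]]$channels))),
       actions = vapply(recs, function(r) as.integer(r$action), 1L),
       rewarded = vapply(recs, function(r) isTRUE(r$rewarded), NA),
       lost = vapply(recs, function(r) isTRUE(r$lost), NA))
}

#' Export the goal-state graph in DOT format
#'
#' Writes the adjacency among goal states (optionally after transitive
#' reduction), each vertex annotated with its backward-induction distance to
#' the nearest goal.
#'
#' @param model a trained \code{denovo_model}.
#' @param path output \code{.dot} file.
#' @param reduce apply \code{\link{transitive_reduction}} first.
#' @return \code{path}, invisibly.
#' @export
export_goal_dot <- function(model, path, reduce = TRUE) {
  top <- model$top
  g <- which(top$goal & top$active)
  adj <- .top_adj(model, exclude_cost = TRUE)
  n <- top$n_states
  A <- matrix(FALSE, length(g), length(g))
  for (k in seq_along(g)) {
    d <- .bfs_dist(adj$out, g[k], model$config$basin_horizon)
    A[match(g[is.finite(d[g])], g), k] <- TRUE
  }
  diag(A) <- FALSE
  if (reduce) A <- transitive_reduction(A)
  dist <- .plan_dist(model, model$config$induction_horizon)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("digraph goals {", con)
  for (k in seq_along(g))
    writeLines(sprintf('  s%d [label="%d (d=%s)"];', g[k], g[k],
                       format(dist[g[k]])), con)
  e <- which(A, arr.ind = TRUE)
  if (nrow(e))
    writeLines(sprintf("  s%d -> s%d;", g[e[, 2L]], g[e[, 1L]]), con)
  writeLines("}", con)
  invisible(path)
}

#' Run the full de novo learning pipeline
#'
#' Executes the three phases (random-play structure learning, reward-gated
#' attractor learning, continual learning by inductive inference) with
#' checkpoints and reports after each, plus the optional final
#' mutual-information-preserving merge.
#'
#' @param config a \code{\link{denovo_config}}.
#' @param out_dir optional directory for artefacts: model archives per phase,
#'   CSV histories, a DOT goal graph, an evidence-bound trace and a JSON
#'   summary.
#' @param merge also compute the merged model.
#' @param progress print progress.
#' @return list with the phase models (\code{structure}, \code{attractor},
#'   \code{continual}, optionally \code{merged}) and a \code{summary} list.
#' @export
run_pipeline <- function(config = denovo_config(), out_dir = NULL,
                         merge = FALSE, progress = FALSE) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  ck <- function(m, nm) if (!is.null(out_dir))
    save_model(m, file.path(out_dir, paste0(nm, ".json")))
  r <- play_frames(new_game(config$game, seed = config$seed), config$frames,
                   "random")
  m1 <- learn_structure(r$obs, config)
  ck(m1, "phase1_structure")
  m2 <- learn_attractor(m1, config, progress = progress)
  ck(m2, "phase2_attractor")
  m3 <- learn_continual(m2, config, progress = progress)
  ck(m3, "phase3_continual")
  mm <- if (merge) merge_preserving_mi(m3) else NULL
  if (merge) ck(mm, "phase4_merged")
  h3 <- m3$history$continual
  summary <- list(
    channels = m1$layout$n_channels,
    levels = n_levels(m1),
    groups = length(m1$factors),
    static_channels = length(m1$static),
    attractor = list(
      converged = isTRUE(m2$attractor_converged),
      epochs_assimilated = nrow(m2$history$attractor),
      states = sum(m2$top$active),
      paths = n_paths(m2),
      goals = sum(m2$top$goal & m2$top$active),
      goal_core = utils::tail(m2$history$attractor$core, 1L)),
    continual = list(
      rewards_per_game = h3$rewards,
      losses_per_game = h3$losses,
      elbo_per_game = h3$elbo,
      states = utils::tail(h3$states, 1L),
      paths = utils::tail(h3$paths, 1L)),
    merged = if (merge) list(states = mm$top$n_states,
                             compression = 1 - mm$top$n_states /
                               sum(m3$top$active)) else NULL)
  if (!is.null(out_dir)) {
    utils::write.csv(m2$history$attractor,
                     file.path(out_dir, "attractor_history.csv"),
                     row.names = FALSE)
    utils::write.csv(h3, file.path(out_dir, "continual_history.csv"),
                     row.names = FALSE)
    el <- m3$history$elbo
    tr <- data.frame(game = rep(seq_along(el), lengths(el)),
                     frame = unlist(lapply(el, seq_along)),
                     nats = unlist(el))
    utils::write.csv(tr, file.path(out_dir, "elbo_trace.csv"),
                     row.names = FALSE)
    export_goal_dot(m3, file.path(out_dir, "goal_graph.dot"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out <- list(structure = m1, attractor = m2, continual = m3,
              merged = mm, summary = summary)
  out[!vapply(out, is.null, NA)]
}
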