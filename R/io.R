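#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) run configuration and applies the defaults:
#' 10 rounds, discount factor 1, neutral `F`/`J` labels. Schema problems
#' are reported with their field path.
#'
#' Recognized fields:
#' * `agents` — list of agent specs, each with `id`, `type`
#'   (`"scripted"` or `"text"`) and, for scripted agents, `kind` plus
#'   optional `option`; for text agents, `persona` plus optional
#'   `label_map`, `moves` and `scot` (the text backend is the offline
#'   mock; live adapters plug in programmatically).
#' * `games` — `"prisoners_dilemma"`, `"battle_of_the_sexes"`,
#'   `"six_families"`, or a path to a game definition file.
#' * `match` — `rounds`, `delta`, `seed`.
#' * `variant` — fields of [make_variant()].
#' * `output_dir` — where transcripts and reports are written.
#'
#' @param path Path to the configuration file.
#' @return An object of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop2("validation", sprintf("no such file: %s", path))
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

validate_config <- function(raw) {
  fail <- function(field, msg) stop2("validation", sprintf("config field `%s`: %s", field, msg))
  if (is.null(raw$agents) || !is.list(raw$agents) || length(raw$agents) == 0L) {
    fail("agents", "must be a non-empty list of agent specs")
  }
  for (i in seq_along(raw$agents)) {
    a <- raw$agents[[i]]
    pre <- sprintf("agents[%d]", i)
    if (is.null(a$id)) fail(paste0(pre, ".id"), "missing")
    if (is.null(a$type) || !a$type %in% c("scripted", "text")) {
      fail(paste0(pre, ".type"), "must be 'scripted' or 'text'")
    }
    if (a$type == "scripted" && is.null(a$kind)) fail(paste0(pre, ".kind"), "missing")
    if (a$type == "text" && is.null(a$persona)) fail(paste0(pre, ".persona"), "missing")
  }
  ids <- vapply(raw$agents, `[[`, "", "id")
  if (anyDuplicated(ids)) fail("agents", "agent ids must be unique")

  games <- raw$games %||% "prisoners_dilemma"
  match_raw <- raw$match %||% list()
  rounds <- match_raw$rounds %||% 10L
  delta <- match_raw$delta %||% 1
  seed <- match_raw$seed %||% 1L
  cfg_match <- tryCatch(match_config(rounds, delta, seed),
                        games2x2_validation_error = function(e) {
                          fail("match", conditionMessage(e))
                        })
  variant <- tryCatch(make_variant(raw$variant %||% list(), seed = seed),
                      games2x2_validation_error = function(e) {
                        fail("variant", conditionMessage(e))
                      })
  structure(
    list(agents = raw$agents, games = games, match = cfg_match,
         variant = variant, output_dir = raw$output_dir %||% "."),
    class = "run_config"
  )
}

#' Serialize a run configuration
#'
#' Writes a [load_config()] object back to YAML such that loading the dump
#' yields an equal configuration.
#'
#' @param config A `run_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  v <- config$variant
  out <- list(
    agents = config$agents,
    games = config$games,
    match = list(rounds = config$match$n_rounds, delta = config$match$delta,
                 seed = config$match$seed),
    variant = Filter(Negate(is.null), list(
      option_labels = v$option_labels, label_order = v$label_order,
      utility = v$utility, cover_story = v$cover_story,
      horizon_disclosed = v$horizon_disclosed,
      fallibility_notice = if (v$fallibility_notice) TRUE,
      opponent_info = v$opponent_info,
      explicit_end_goal = if (v$explicit_end_goal) TRUE
    )),
    output_dir = config$output_dir
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Instantiate the agents of a configuration
#'
#' @param config A `run_config`.
#' @return Named list of [agent_policy()] objects keyed by agent id.
#' @export
config_agents <- function(config) {
  out <- lapply(config$agents, function(a) {
    if (a$type == "scripted") {
      scripted_agent(a$kind, option = a$option, name = a$id)
    } else {
      lm <- if (!is.null(a$label_map)) unlist(a$label_map)
      backend <- mock_backend(a$persona, label_map = lm,
                              moves = if (!is.null(a$moves)) as.character(a$moves),
                              description = a$id)
      if (isTRUE(a$scot)) scot_agent(backend, name = a$id)
      else text_agent(backend, name = a$id)
    }
  })
  stats::setNames(out, vapply(config$agents, `[[`, "", "id"))
}

#' Resolve the game set of a configuration
#'
#' @param config A `run_config`.
#' @return Named list of [payoff_matrix()] objects.
#' @export
config_games <- function(config) {
  sel <- config$games
  if (identical(sel, "six_families")) return(six_family_games())
  if (sel %in% c("prisoners_dilemma", "battle_of_the_sexes")) {
    g <- canonical_game(sel)
    attr(g, "family") <- if (sel == "prisoners_dilemma") "pd_family" else "biased"
    return(stats::setNames(list(g), sel))
  }
  if (file.exists(sel)) {
    return(stats::setNames(list(read_game(sel)), tools::file_path_sans_ext(basename(sel))))
  }
  stop2("validation", sprintf("config field `games`: unknown selector '%s'", sel))
}

# --- transcript persistence (JSON Lines) ------------------------------------

serialize_matrix <- function(m) {
  list(options_p1 = m$options_p1, options_p2 = m$options_p2,
       cells = lapply(1:4, function(k) {
         i <- (k - 1) %/% 2 + 1; j <- (k - 1) %% 2 + 1
         c(m$p1[i, j], m$p2[i, j])
       }),
       action_roles = m$action_roles)
}

deserialize_matrix <- function(x) {
  payoff_matrix(lapply(x$cells, function(p) as.numeric(unlist(p))),
                as.character(x$options_p1), as.character(x$options_p2),
                action_roles = if (length(x$action_roles))
                  lapply(x$action_roles, as.integer))
}

serialize_variant <- function(v) {
  Filter(Negate(is.null), list(
    option_labels = v$option_labels, label_order = v$label_order,
    utility = v$utility, cover_story = v$cover_story,
    horizon_disclosed = v$horizon_disclosed,
    fallibility_notice = v$fallibility_notice,
    opponent_info = v$opponent_info, explicit_end_goal = v$explicit_end_goal,
    seed = v$seed
  ))
}

deserialize_variant <- function(x) {
  structure(list(
    option_labels = as.character(x$option_labels),
    label_order = x$label_order, utility = x$utility,
    cover_story = x$cover_story,
    horizon_disclosed = if (!is.null(x$horizon_disclosed)) as.integer(x$horizon_disclosed),
    fallibility_notice = isTRUE(x$fallibility_notice),
    opponent_info = x$opponent_info,
    explicit_end_goal = isTRUE(x$explicit_end_goal),
    seed = if (!is.null(x$seed)) as.integer(x$seed)
  ), class = "prompt_variant")
}

#' Write transcripts as a JSON Lines archive
#'
#' Each transcript becomes one header line (matrix, agents, variants,
#' seed, status) followed by one line per round; [read_transcripts()]
#' reconstructs the transcripts losslessly.
#'
#' @param transcripts A list of transcripts.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(transcripts, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_along(transcripts)) {
    tr <- transcripts[[k]]
    header <- list(type = "header", match_id = k,
                   matrix = serialize_matrix(tr$matrix),
                   agents = tr$agent_names,
                   variant_p1 = serialize_variant(tr$variant_p1),
                   variant_p2 = serialize_variant(tr$variant_p2),
                   seed = tr$seed, status = tr$status,
                   abort_round = tr$abort_round, abort_reason = tr$abort_reason,
                   n_rounds = length(tr$rounds))
    writeLines(jsonlite::toJSON(Filter(Negate(is.null), header),
                                auto_unbox = TRUE, digits = NA), con)
    for (rec in tr$rounds) {
      line <- list(type = "round", match_id = k, round = rec$round,
                   action_p1 = rec$action_p1, action_p2 = rec$action_p2,
                   payoff_p1 = rec$payoff_p1, payoff_p2 = rec$payoff_p2,
                   prediction_p1 = rec$prediction_p1,
                   prediction_p2 = rec$prediction_p2,
                   distribution_p1 = as.list(rec$distribution_p1),
                   distribution_p2 = as.list(rec$distribution_p2))
      line <- Filter(function(x) !is.null(x) && length(x) > 0, line)
      writeLines(jsonlite::toJSON(line, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' Read a JSON Lines transcript archive
#'
#' Corrupt lines are skipped and reported (with their line numbers) in the
#' `"errors"` attribute of the result; intact transcripts are still
#' returned.
#'
#' @param path Archive path.
#' @return A list of transcripts; attribute `"errors"` holds a data frame
#'   with columns `line` and `message` (zero rows when the file is clean).
#' @export
read_transcripts <- function(path) {
  if (!file.exists(path)) stop2("validation", sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  transcripts <- list()
  errors <- list()
  current <- NULL
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE,
                                       simplifyMatrix = FALSE,
                                       simplifyDataFrame = FALSE),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      errors[[length(errors) + 1L]] <- data.frame(
        line = i, message = conditionMessage(rec), stringsAsFactors = FALSE)
      next
    }
    if (identical(rec$type, "header")) {
      tr <- new_transcript(deserialize_matrix(rec$matrix),
                           as.character(rec$agents),
                           deserialize_variant(rec$variant_p1),
                           deserialize_variant(rec$variant_p2),
                           as.integer(rec$seed))
      tr$status <- rec$status
      if (!is.null(rec$abort_round)) tr$abort_round <- as.integer(rec$abort_round)
      if (!is.null(rec$abort_reason)) tr$abort_reason <- rec$abort_reason
      transcripts[[length(transcripts) + 1L]] <- tr
      current <- length(transcripts)
    } else if (identical(rec$type, "round")) {
      if (is.null(current)) {
        errors[[length(errors) + 1L]] <- data.frame(
          line = i, message = "round line before any header", stringsAsFactors = FALSE)
        next
      }
      round <- list(round = as.integer(rec$round),
                    action_p1 = rec$action_p1, action_p2 = rec$action_p2,
                    payoff_p1 = as.numeric(rec$payoff_p1),
                    payoff_p2 = as.numeric(rec$payoff_p2))
      for (f in c("prediction_p1", "prediction_p2")) {
        if (!is.null(rec[[f]])) {
          round[[f]] <- list(round = as.integer(rec[[f]]$round),
                             predicted = rec[[f]]$predicted,
                             actual = rec[[f]]$actual)
        }
      }
      for (f in c("distribution_p1", "distribution_p2")) {
        if (!is.null(rec[[f]])) round[[f]] <- unlist(rec[[f]])
      }
      transcripts[[current]]$rounds[[round$round]] <- round
    } else {
      errors[[length(errors) + 1L]] <- data.frame(
        line = i, message = "unknown record type", stringsAsFactors = FALSE)
    }
  }
  attr(transcripts, "errors") <- if (length(errors)) do.call(rbind, errors)
    else data.frame(line = integer(0), message = character(0), stringsAsFactors = FALSE)
  transcripts
}
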