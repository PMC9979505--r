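#' Policy configuration for turning counterfactual panels into prescriptions
#'
#' @param xi Inverse temperature of the randomized softmax policy (>= 0);
#'   0 gives a uniform draw over allowed options, large values concentrate on
#'   the minimum-predicted-SBP option.
#' @param delta Switch threshold in mmHg: the recommended option replaces the
#'   current regimen only when the predicted improvement
#'   `yhat_current - yhat_candidate` reaches `delta`.
#' @param mode `"randomized"` (seeded softmax draw) or `"deterministic"`
#'   (argmin of predicted SBP).
#' @param soft_preference_weight Multiplicative boost (>= 1) applied to
#'   options favored by the advisory rules (diabetes -> ACEi/ARB, systolic
#'   heart failure -> beta-blocker); 1 disables the boost.
#' @param seed Integer seed for the randomized draws.
#' @return An object of class `bp_policy_config`.
#' @export
policy_config <- function(xi = 0.25, delta = 0, mode = c("randomized",
                                                         "deterministic"),
                          soft_preference_weight = 1.5, seed = 1L) {
  mode <- match.arg(mode)
  if (xi < 0) abort("`xi` must be >= 0.", class = "bp_config_error")
  if (delta < 0) abort("`delta` must be >= 0.", class = "bp_config_error")
  if (soft_preference_weight < 1) {
    abort("`soft_preference_weight` must be >= 1.", class = "bp_config_error")
  }
  structure(list(xi = xi, delta = delta, mode = mode,
                 soft_preference_weight = soft_preference_weight,
                 seed = as.integer(seed)),
            class = "bp_policy_config")
}

bp_hard_rules <- function() {
  tibble::tribble(
    ~rule_id,          ~description,
    "low_pulse",       "pulse < 60: no beta-blocker",
    "high_potassium",  "potassium > 4.5: no ACEi/ARB",
    "high_creatinine", "creatinine >= 2: no ACEi/ARB/thiazide",
    "very_high_potassium", "potassium > 5: no MRA"
  )
}

#' Apply the clinical contraindication and preference rules to one visit
#'
#' Hard rules remove menu options: pulse below 60 excludes beta-blockers;
#' potassium above 4.5 excludes ACEi and ARB; creatinine of 2 or more
#' excludes ACEi, ARB and thiazide; potassium above 5 excludes MRA. An option
#' containing any contraindicated class (including a combination current
#' regimen) is excluded. Soft rules only annotate: diabetes prefers ACEi/ARB
#' and systolic heart failure prefers a beta-blocker. Missing labs leave the
#' corresponding rule unevaluated and flag the visit `rule_unevaluable`.
#'
#' @param visit One visit row (needs `pulse`, `potassium`, `creatinine`,
#'   `diabetes`, `systolic_hf`, `regimen`).
#' @param options Menu option labels (class labels, possibly `"current"`).
#' @return List with `allowed` (labels), `excluded` (tibble option/rule_id),
#'   `soft_flags` (preferred class labels), `rule_unevaluable`.
#' @export
apply_rules <- function(visit, options) {
  pulse <- visit$pulse %||% NA_real_
  pot <- visit$potassium %||% NA_real_
  creat <- visit$creatinine %||% NA_real_
  banned <- list()
  if (isTRUE(pulse < 60)) banned$low_pulse <- "BetaBlocker"
  if (isTRUE(pot > 4.5)) banned$high_potassium <- c("ACEi", "ARB")
  if (isTRUE(creat >= 2)) banned$high_creatinine <- c("ACEi", "ARB", "Thiazide")
  if (isTRUE(pot > 5)) banned$very_high_potassium <- "MRA"

  regimen <- if (is.list(visit$regimen)) visit$regimen[[1]] else visit$regimen
  option_classes <- function(opt) if (opt == "current") regimen else opt
  excl <- purrr::imap(banned, function(cls, rid) {
    hit <- options[purrr::map_lgl(options,
                                  ~ any(option_classes(.x) %in% cls))]
    if (length(hit)) tibble(option = hit, rule_id = rid) else NULL
  })
  excluded <- bind_rows(excl)
  if (nrow(excluded) == 0) {
    excluded <- tibble(option = character(0), rule_id = character(0))
  }
  allowed <- setdiff(options, excluded$option)

  soft <- character(0)
  if (isTRUE((visit$diabetes %||% 0) == 1)) soft <- c(soft, "ACEi", "ARB")
  if (isTRUE((visit$systolic_hf %||% 0) == 1)) soft <- c(soft, "BetaBlocker")

  list(allowed = allowed,
       excluded = excluded,
       soft_flags = intersect(soft, options),
       rule_unevaluable = anyNA(c(pulse, pot, creat)))
}

#' Softmax recommendation probabilities over the allowed menu
#'
#' `p_m` is proportional to `w_m * exp(-xi * yhat_m)` over the allowed
#' options, where `w_m` is the soft-preference boost for flagged options and
#' 1 otherwise; computed with a max-shift for numerical stability. Options
#' excluded by a hard rule receive probability exactly 0.
#'
#' @param yhat Named vector of predicted next-period SBP per option.
#' @param xi Inverse temperature (>= 0).
#' @param allowed Labels of allowed options (default: all).
#' @param boosts Labels of soft-preferred options.
#' @param boost_weight Multiplier applied to boosted options.
#' @return Named probability vector over all options in `yhat`; zeros for
#'   disallowed ones.
#' @export
softmax_policy <- function(yhat, xi, allowed = names(yhat),
                           boosts = character(0), boost_weight = 1) {
  if (xi < 0) abort("`xi` must be >= 0.", class = "bp_config_error")
  if (length(allowed) == 0) {
    abort("Allowed option set is empty.", class = "bp_config_error")
  }
  p <- setNames(rep(0, length(yhat)), names(yhat))
  v <- -xi * yhat[allowed]
  v <- v - max(v)
  w <- ifelse(allowed %in% boosts, boost_weight, 1)
  e <- w * exp(v)
  p[allowed] <- e / sum(e)
  p
}

#' Turn counterfactual panels into per-visit prescription recommendations
#'
#' For each visit: the clinical rules prune the menu, the softmax policy
#' scores the allowed options, a candidate is selected (argmin of predicted
#' SBP in deterministic mode, a seeded softmax draw in randomized mode), and
#' the candidate replaces the current regimen only when the predicted
#' improvement reaches the switch threshold `delta`. When the rules exclude
#' every option, the recommendation falls back to the current regimen with
#' status `"all_excluded"`.
#'
#' @param panels A `bp_panel` from [build_panels()].
#' @param visits The visit table the panel was built for.
#' @param config A [policy_config()].
#' @return A tibble of class `bp_recommendations`: one row per visit with the
#'   chosen option, `kept_current`, probability and exclusion list-columns,
#'   and per-visit predicted SBP under the chosen and current options.
#' @export
recommend <- function(panels, visits, config = policy_config()) {
  cur <- current_predictions(panels, visits)
  pan_by_visit <- split(as_tibble(panels)[c("visit_id", "option", "estimate")],
                        panels$visit_id)
  set.seed(config$seed)
  draw_u <- setNames(runif(nrow(visits)), visits$visit_id)

  rows <- purrr::map(seq_len(nrow(visits)), function(i) {
    vid <- visits$visit_id[i]
    pan <- pan_by_visit[[vid]]
    if (is.null(pan)) return(NULL)
    visit <- visits[i, ]
    yhat <- setNames(pan$estimate, pan$option)
    rules <- apply_rules(visit, pan$option)
    cur_lbl <- if (length(visit$regimen[[1]]) == 1L) visit$regimen[[1]]
               else "current"
    y_cur <- cur$current_estimate[match(vid, cur$visit_id)]

    if (length(rules$allowed) == 0) {
      return(tibble(
        visit_id = vid, chosen = cur_lbl, kept_current = TRUE,
        status = "all_excluded", rule_unevaluable = rules$rule_unevaluable,
        yhat_chosen = y_cur, yhat_current = y_cur,
        probabilities = list(setNames(rep(0, length(yhat)), names(yhat))),
        excluded = list(rules$excluded), soft_flags = list(rules$soft_flags)
      ))
    }

    probs <- softmax_policy(yhat, config$xi, rules$allowed, rules$soft_flags,
                            config$soft_preference_weight)
    candidate <- if (config$mode == "deterministic") {
      al <- rules$allowed[order(yhat[rules$allowed], rules$allowed)]
      al[1]
    } else {
      al <- names(probs)[probs > 0]
      al[findInterval(draw_u[[vid]], cumsum(probs[al]),
                      rightmost.closed = TRUE) + 1L]
    }

    chosen <- candidate
    kept <- identical(candidate, cur_lbl)
    # keep-current applies only when the current option is itself allowed:
    # a contraindicated current regimen must be switched away from
    cur_allowed <- cur_lbl %in% rules$allowed ||
      !cur_lbl %in% c(rules$excluded$option, names(yhat))
    if (cur_allowed && !is.na(y_cur) &&
        (y_cur - yhat[[candidate]]) < config$delta) {
      kept <- TRUE
      chosen <- cur_lbl
    }
    tibble(
      visit_id = vid, chosen = chosen, kept_current = kept,
      status = "ok", rule_unevaluable = rules$rule_unevaluable,
      yhat_chosen = if (chosen %in% names(yhat)) unname(yhat[[chosen]])
                    else y_cur,
      yhat_current = y_cur,
      probabilities = list(probs),
      excluded = list(rules$excluded), soft_flags = list(rules$soft_flags)
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("bp_recommendations", class(out))
  attr(out, "config") <- config
  out
}

#' Long-format recommendation probabilities
#' @param recommendations A `bp_recommendations` tibble.
#' @return Tibble `visit_id`, `option`, `probability`.
#' @export
recommendation_probs <- function(recommendations) {
  purrr::map2_dfr(recommendations$visit_id, recommendations$probabilities,
                  ~ tibble(visit_id = .x, option = names(.y),
                           probability = unname(.y)))
}
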