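# Clinical triage rule engine: which testing modality (rapid hotspot
# cartridge first, comprehensive NGS first, or cartridge as orthogonal
# confirmation) fits a given clinical context. Rules live in an
# ordered YAML/JSON config; first match wins and a terminal default is
# mandatory, so every context yields an auditable recommendation.

TRIAGE_VOCAB <- list(
  tumor_type = c("cutaneous melanoma", "colorectal cancer",
                 "lung adenocarcinoma", "hairy cell leukemia", "AML",
                 "other"),
  care_setting = c("community_no_onsite_molecular", "academic_with_ngs"),
  tissue_adequacy = c("adequate", "scant"),
  urgency = c("routine", "urgent"),
  prior_result = c("none", "idylla_negative", "ngs_ambiguous")
)

TRIAGE_MODALITIES <- c("idylla_first_line", "ngs_first",
                       "idylla_orthogonal_confirmation")
TRIAGE_REFLEX <- c("none", "reflex_to_ngs_if_negative")

#' Construct a triage decision context
#'
#' @param tumor_type One of the controlled tumor-type vocabulary (see
#'   `TRIAGE_VOCAB$tumor_type`).
#' @param genes_in_question Gene symbols under clinical question.
#' @param care_setting `"community_no_onsite_molecular"` or
#'   `"academic_with_ngs"`.
#' @param tissue_adequacy `"adequate"` or `"scant"`.
#' @param urgency `"routine"` or `"urgent"`.
#' @param prior_result `"none"`, `"idylla_negative"` or
#'   `"ngs_ambiguous"`.
#' @return An object of class `decision_context`.
#' @export
decision_context <- function(tumor_type,
                             genes_in_question = character(0),
                             care_setting,
                             tissue_adequacy = "adequate",
                             urgency = "routine",
                             prior_result = "none") {
  ctx <- list(tumor_type = tumor_type,
              genes_in_question = toupper(genes_in_question),
              care_setting = care_setting,
              tissue_adequacy = tissue_adequacy,
              urgency = urgency,
              prior_result = prior_result)
  for (field in names(TRIAGE_VOCAB)) {
    val <- ctx[[field]]
    if (length(val) != 1L || !(val %in% TRIAGE_VOCAB[[field]])) {
      ps_error(sprintf("invalid %s: '%s' (allowed: %s)", field,
                       paste(val, collapse = ","),
                       paste(TRIAGE_VOCAB[[field]], collapse = ", ")),
               "panelscope_config_error")
    }
  }
  structure(ctx, class = "decision_context")
}

.validate_rule <- function(rule, i) {
  for (need in c("rule_id", "action", "rationale")) {
    if (is.null(rule[[need]])) {
      ps_error(sprintf("rule %d lacks '%s'", i, need),
               "panelscope_config_error")
    }
  }
  if (is.null(rule$match)) rule$match <- list()
  known <- c(names(TRIAGE_VOCAB), "genes_in_question")
  for (field in names(rule$match)) {
    if (!(field %in% known)) {
      ps_error(sprintf("rule '%s': unknown match field '%s'", rule$rule_id,
                       field), "panelscope_config_error")
    }
    if (field %in% names(TRIAGE_VOCAB)) {
      bad <- setdiff(unlist(rule$match[[field]]), TRIAGE_VOCAB[[field]])
      if (length(bad)) {
        ps_error(sprintf("rule '%s': value(s) %s outside the %s vocabulary",
                         rule$rule_id, paste(bad, collapse = ", "), field),
                 "panelscope_config_error")
      }
    }
  }
  if (!(rule$action$modality %in% TRIAGE_MODALITIES)) {
    ps_error(sprintf("rule '%s': unknown modality '%s'", rule$rule_id,
                     rule$action$modality), "panelscope_config_error")
  }
  reflex <- rule$action$reflex %||% "none"
  if (!(reflex %in% TRIAGE_REFLEX)) {
    ps_error(sprintf("rule '%s': unknown reflex '%s'", rule$rule_id, reflex),
             "panelscope_config_error")
  }
  rule$action$reflex <- reflex
  rule
}

#' Load a triage ruleset
#'
#' Reads an ordered rule list from YAML or JSON. Each rule carries
#' `rule_id`, a `match` block of context-field conditions (a missing
#' block matches everything), an `action` (`modality`, optional
#' `reflex`) and a human-readable `rationale`. Rules are evaluated in
#' file order, first match wins; the final rule must be a terminal
#' default (empty match) so the ruleset is total. Off-vocabulary
#' values anywhere fail the load.
#'
#' @param path Path to the ruleset file (`.yaml`/`.yml`/`.json`).
#' @return An object of class `triage_ruleset` (ordered list of
#'   validated rules).
#' @examples
#' rules <- load_ruleset(system.file("extdata", "default_ruleset.yaml",
#'                                   package = "panelscope"))
#' @export
load_ruleset <- function(path) {
  if (!file.exists(path)) {
    ps_error(sprintf("ruleset file not found: %s", path),
             "panelscope_io_error")
  }
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  rules <- doc$rules %||% doc
  if (!is.list(rules) || !length(rules)) {
    ps_error(sprintf("no rules found in %s", path), "panelscope_config_error")
  }
  rules <- lapply(seq_along(rules), function(i) .validate_rule(rules[[i]], i))
  last <- rules[[length(rules)]]
  if (length(last$match %||% list())) {
    ps_error("ruleset lacks a terminal default rule (final rule must have an empty match)",
             "panelscope_config_error")
  }
  structure(rules, class = "triage_ruleset")
}

#' @export
print.triage_ruleset <- function(x, ...) {
  cat("<triage_ruleset> ", length(x), " rules: ",
      paste(vapply(x, function(r) r$rule_id, character(1)), collapse = " > "),
      "\n", sep = "")
  invisible(x)
}

.rule_matches <- function(rule, context) {
  for (field in names(rule$match)) {
    want <- unlist(rule$match[[field]])
    if (field == "genes_in_question") {
      if (!length(intersect(toupper(want), context$genes_in_question))) {
        return(FALSE)
      }
    } else if (!(context[[field]] %in% want)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Recommend a testing modality for a clinical context
#'
#' Evaluates the ruleset in order and returns the first matching
#' rule's action; the terminal default guarantees an answer. The
#' recommendation always cites the rule it came from, so decisions
#' are auditable.
#'
#' @param context A `decision_context`.
#' @param rules A `triage_ruleset` from [load_ruleset()].
#' @return An object of class `triage_recommendation`: `modality`,
#'   `reflex`, `rationale`, `rule_id`.
#' @examples
#' rules <- load_ruleset(system.file("extdata", "default_ruleset.yaml",
#'                                   package = "panelscope"))
#' recommend(decision_context("cutaneous melanoma", "BRAF",
#'                            "community_no_onsite_molecular"), rules)
#' @export
recommend <- function(context, rules) {
  stopifnot(inherits(context, "decision_context"),
            inherits(rules, "triage_ruleset"))
  for (rule in rules) {
    if (.rule_matches(rule, context)) {
      return(structure(list(modality = rule$action$modality,
                            reflex = rule$action$reflex,
                            rationale = rule$rationale,
                            rule_id = rule$rule_id),
                       class = "triage_recommendation"))
    }
  }
  # unreachable: load_ruleset enforces a terminal default
  ps_error("no rule matched and no terminal default present",
           "panelscope_config_error")
}

#' @export
print.triage_recommendation <- function(x, ...) {
  cat("<triage_recommendation> ", x$modality,
      if (x$reflex != "none") paste0(" (+", x$reflex, ")"), "\n",
      "  rule: ", x$rule_id, "\n  rationale: ", x$rationale, "\n", sep = "")
  invisible(x)
}

#' @export
format.triage_recommendation <- function(x, ...) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, pretty = TRUE)
}
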