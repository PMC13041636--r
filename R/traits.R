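# Declarative trait-marker validation: rules map genotype predicates at
# candidate markers to predicted phenotype classes; the engine scores each
# rule against observed phenotypes.

TRAIT_PREDICATES <- c(
  "allele_present", "allele_absent", "homozygous_B", "homozygous_A",
  "haplotype_match"
)

#' Define a trait-prediction rule
#'
#' A rule maps a genotype predicate at one or more markers to a predicted
#' phenotype class. Predicates: `allele_present` (at least one B allele,
#' dominant), `allele_absent`, `homozygous_B` (recessive), `homozygous_A`,
#' and `haplotype_match` (the calls at `marker_ids` equal `expected`,
#' positions marked `"any"` ignored).
#'
#' @param rule_id Rule identifier.
#' @param trait Phenotype column the rule predicts.
#' @param marker_ids Marker id(s); single marker for allele predicates.
#' @param predicate One of the predicate names above.
#' @param predicted_class Phenotype class predicted when the predicate
#'   holds.
#' @param else_class Optional class predicted when the predicate fails;
#'   when `NA`, a sample failing the predicate is counted correct iff its
#'   observed class differs from `predicted_class`.
#' @param expected For `haplotype_match`: expected call vector over
#'   `AA`/`AB`/`BB`/`any`, same length as `marker_ids`.
#' @param applicability Optional character vector of `taxon_class` values
#'   the rule applies to.
#' @return A list of class `trait_rule`.
#' @export
trait_rule <- function(rule_id, trait, marker_ids, predicate, predicted_class,
                       else_class = NA_character_, expected = NULL,
                       applicability = NULL) {
  if (!predicate %in% TRAIT_PREDICATES) {
    stop("unknown predicate: ", predicate, call. = FALSE)
  }
  if (!length(marker_ids)) stop("marker_ids must be non-empty", call. = FALSE)
  if (predicate == "haplotype_match") {
    if (is.null(expected) || length(expected) != length(marker_ids)) {
      stop("haplotype_match needs an expected vector matching marker_ids", call. = FALSE)
    }
    if (!all(expected %in% c("AA", "AB", "BB", "any"))) {
      stop("expected vector entries must be AA, AB, BB or any", call. = FALSE)
    }
  }
  structure(
    list(
      rule_id = rule_id, trait = trait, marker_ids = marker_ids,
      predicate = predicate, predicted_class = predicted_class,
      else_class = else_class, expected = expected,
      applicability = applicability
    ),
    class = "trait_rule"
  )
}

# per-sample predicate outcome; NA when a required call is missing
rule_predicate <- function(gm, rule) {
  m <- unclass(as_genotype_matrix(gm))
  if (rule$predicate == "haplotype_match") {
    req <- rule$expected != "any"
    mk <- rule$marker_ids[req]
    exp <- rule$expected[req]
    sub <- m[, mk, drop = FALSE]
    any_nc <- rowSums(sub == "NC") > 0
    hit <- rowSums(sub == matrix(exp, nrow(sub), length(exp), byrow = TRUE)) == length(exp)
    return(ifelse(any_nc, NA, hit))
  }
  g <- m[, rule$marker_ids[1]]
  out <- switch(rule$predicate,
    allele_present = g %in% c("AB", "BB"),
    allele_absent = g == "AA",
    homozygous_B = g == "BB",
    homozygous_A = g == "AA"
  )
  ifelse(g == "NC", NA, out)
}

apply_collapse <- function(x, collapse) {
  if (is.null(collapse)) {
    return(x)
  }
  ifelse(x %in% names(collapse), unname(collapse[x]), x)
}

#' Evaluate a trait rule against observed phenotypes
#'
#' Samples lacking the phenotype, outside the rule's applicability, or
#' with a no-call at a required marker are excluded from `n_evaluable`.
#' An optional class-collapse map (named character vector, e.g. OIV-225
#' berry-colour codes to `colored`/`non_colored`) is applied to observed
#' classes before comparison.
#'
#' @param gm A [genotype_matrix()].
#' @param rule A [trait_rule()].
#' @param phenotypes Tibble with `sample_id`, the rule's trait column and
#'   optionally `taxon_class`.
#' @param collapse Optional named character vector mapping raw phenotype
#'   classes to collapsed classes.
#' @param detail Return the per-sample table instead of the summary row?
#' @return A one-row tibble: `rule_id`, `trait`, `n_evaluable`,
#'   `n_correct`, `n_wrong`, `fully_predictive`, `wrong_sample_ids`
#'   (list-column); or the per-sample detail tibble when `detail = TRUE`.
#' @export
evaluate_rule <- function(gm, rule, phenotypes, collapse = NULL, detail = FALSE) {
  stopifnot(inherits(rule, "trait_rule"))
  gm <- as_genotype_matrix(gm)
  pred <- rule_predicate(gm, rule)
  obs <- phenotypes[[rule$trait]][match(sample_ids(gm), phenotypes$sample_id)]
  obs <- apply_collapse(obs, collapse)
  applicable <- rep(TRUE, nrow(gm))
  if (!is.null(rule$applicability) && "taxon_class" %in% names(phenotypes)) {
    tc <- phenotypes$taxon_class[match(sample_ids(gm), phenotypes$sample_id)]
    applicable <- !is.na(tc) & tc %in% rule$applicability
  }
  evaluable <- applicable & !is.na(pred) & !is.na(obs)
  predicted <- if (!is.na(rule$else_class)) {
    ifelse(pred, rule$predicted_class, rule$else_class)
  } else {
    NA_character_
  }
  correct <- if (!is.na(rule$else_class)) {
    predicted == obs
  } else {
    pred == (obs == rule$predicted_class)
  }
  per_sample <- tibble::tibble(
    sample_id = sample_ids(gm),
    predicate = pred, observed = obs, predicted = predicted,
    evaluable = evaluable,
    correct = ifelse(evaluable, correct, NA)
  )
  if (detail) {
    return(per_sample)
  }
  ev <- per_sample[per_sample$evaluable, , drop = FALSE]
  n_wrong <- sum(!ev$correct)
  tibble::tibble(
    rule_id = rule$rule_id, trait = rule$trait,
    n_evaluable = nrow(ev),
    n_correct = as.integer(sum(ev$correct)),
    n_wrong = as.integer(n_wrong),
    fully_predictive = nrow(ev) > 0 && n_wrong == 0,
    wrong_sample_ids = list(ev$sample_id[!ev$correct])
  )
}

#' Build the standard flower-sex marker rules
#'
#' Female-sterility markers tag the dominant male-determining haplotype
#' (`allele_present`, predicting male flowers); male-sterility markers tag
#' the female-determining haplotype, which is recessive (`homozygous_B`,
#' predicting female flowers).
#'
#' @param roles Tibble `marker_id`, `role` with roles `female_sterility`
#'   or `male_sterility`.
#' @return A list of [trait_rule()] objects, each carrying a `role` field.
#' @export
sex_rules_from_roles <- function(roles) {
  purrr::pmap(roles, function(marker_id, role) {
    r <- if (role == "female_sterility") {
      trait_rule(
        rule_id = marker_id, trait = "flower_sex", marker_ids = marker_id,
        predicate = "allele_present", predicted_class = "male"
      )
    } else {
      trait_rule(
        rule_id = marker_id, trait = "flower_sex", marker_ids = marker_id,
        predicate = "homozygous_B", predicted_class = "female"
      )
    }
    r$role <- role
    r
  })
}

#' Evaluate the flower-sex marker panel
#'
#' Scores each sex-associated marker individually (is its predicate fully
#' predictive of the sterility class it tags?) and combines the two marker
#' sets into a per-sample sex call: male when female-sterility is
#' indicated and male-sterility is not; female in the reverse case;
#' hermaphrodite when neither; a sample indicating both is flagged as a
#' conflict and excluded from accuracy. Samples listed in `drop_samples`
#' (e.g. duplicate clones) are removed before panel-level counts.
#'
#' @param gm A [genotype_matrix()].
#' @param sex_rules List of rules from [sex_rules_from_roles()].
#' @param phenotypes Tibble with `sample_id` and `flower_sex`.
#' @param drop_samples Sample ids excluded from the panel counts.
#' @return A list: `per_marker` (rule evaluations with `role`),
#'   `combined` (per-sample calls with `correct`), `n_fully_predictive`,
#'   `combined_accuracy`.
#' @export
evaluate_flower_sex_panel <- function(gm, sex_rules, phenotypes,
                                      drop_samples = character(0)) {
  gm <- as_genotype_matrix(gm)
  keep <- setdiff(sample_ids(gm), drop_samples)
  gm <- gm[keep, ]
  per_marker <- purrr::map_dfr(sex_rules, function(r) {
    dplyr::mutate(evaluate_rule(gm, r, phenotypes), role = r$role)
  })
  fem_rules <- sex_rules[vapply(sex_rules, function(r) r$role == "female_sterility", logical(1))]
  male_rules <- sex_rules[vapply(sex_rules, function(r) r$role == "male_sterility", logical(1))]
  ind <- function(rules) {
    mat <- vapply(rules, function(r) rule_predicate(gm, r), logical(nrow(gm)))
    any_true <- rowSums(mat, na.rm = TRUE) > 0
    any_na <- rowSums(is.na(mat)) > 0
    ifelse(any_true, TRUE, ifelse(any_na, NA, FALSE))
  }
  fem <- ind(fem_rules)
  mal <- ind(male_rules)
  call <- dplyr::case_when(
    is.na(fem) | is.na(mal) ~ NA_character_,
    fem & mal ~ "conflict",
    fem ~ "male",
    mal ~ "female",
    .default = "hermaphrodite"
  )
  obs <- phenotypes$flower_sex[match(sample_ids(gm), phenotypes$sample_id)]
  combined <- tibble::tibble(
    sample_id = sample_ids(gm),
    female_sterility_indicated = fem,
    male_sterility_indicated = mal,
    combined_call = call,
    observed = obs,
    correct = ifelse(
      is.na(call) | call == "conflict" | is.na(obs), NA, call == obs
    )
  )
  acc <- mean(combined$correct, na.rm = TRUE)
  list(
    per_marker = per_marker,
    combined = combined,
    n_fully_predictive = sum(per_marker$fully_predictive),
    combined_accuracy = acc
  )
}

#' Evaluate a multi-marker haplotype rule
#'
#' A carrier is a sample matching the expected call vector at every
#' non-`any` position; a no-call at a required position makes the sample
#' non-evaluable. Concordance with the phenotype class is reported for
#' carriers with phenotype data; carriers without phenotype are listed
#' separately.
#'
#' @inheritParams evaluate_rule
#' @return A list: `evaluation` (one-row tibble as [evaluate_rule()]),
#'   `carriers`, `carriers_without_phenotype`, `non_evaluable_samples`.
#' @export
evaluate_haplotype_rule <- function(gm, rule, phenotypes = NULL, collapse = NULL) {
  stopifnot(rule$predicate == "haplotype_match")
  gm <- as_genotype_matrix(gm)
  pred <- rule_predicate(gm, rule)
  carriers <- sample_ids(gm)[!is.na(pred) & pred]
  non_eval <- sample_ids(gm)[is.na(pred)]
  if (is.null(phenotypes) || !rule$trait %in% names(phenotypes)) {
    return(list(
      evaluation = NULL, carriers = carriers,
      carriers_without_phenotype = carriers,
      non_evaluable_samples = non_eval
    ))
  }
  obs <- phenotypes[[rule$trait]][match(carriers, phenotypes$sample_id)]
  list(
    evaluation = evaluate_rule(gm, rule, phenotypes, collapse = collapse),
    carriers = carriers,
    carriers_without_phenotype = carriers[is.na(obs)],
    non_evaluable_samples = non_eval
  )
}
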