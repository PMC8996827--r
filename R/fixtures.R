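# Synthetic labeled reactions: small template library with substituent
# slots, instantiated by seeded sampling and validated through the parser,
# plus a rule-based additive yield generator. These stand in for downstream
# benchmark corpora so that every harness is testable without any download;
# they are synthetic and make no claim of chemical realism.

#' The built-in reaction template library
#'
#' Each template is a reaction SMILES skeleton with `{A}`/`{B}` substituent
#' slots; substituents from [substituent_pool()] are spliced in as plain
#' string substitution and the result is validated by [parse_reaction()]
#' (invalid combinations are rejected and resampled).
#'
#' @return data frame with columns `name`, `left`, `reagent`, `right`.
#' @export
reaction_templates <- function() {
  data.frame(
    name = c("esterification", "amide_coupling", "n_alkylation",
             "suzuki_coupling", "williamson_ether", "reductive_amination"),
    left = c("{A}C(=O)O.{B}O",
             "{A}C(=O)O.{B}N",
             "{A}Br.{B}N",
             "{A}B(O)O.{B}Br",
             "{A}O.{B}Br",
             "{A}C=O.{B}N"),
    reagent = c("OS(=O)(=O)O",
                "CCN=C=NCCCN(C)C",
                "CCN(CC)CC",
                "c1ccc(cc1)P(c1ccccc1)c1ccccc1",
                "[K+].[OH-]",
                "[Na+].[BH4-]"),
    right = c("{A}C(=O)O{B}.O",
              "{A}C(=O)N{B}.O",
              "{B}N{A}.Br",
              "{A}{B}.OB(O)O.Br",
              "{A}O{B}.Br",
              "{A}CN{B}.O"),
    stringsAsFactors = FALSE)
}

#' The built-in substituent pool
#'
#' Small alkyl and aryl SMILES fragments written so that they stay valid
#' whether spliced before or after an attachment atom.
#'
#' @return character vector of substituent SMILES fragments.
#' @export
substituent_pool <- function() {
  c("C", "CC", "CCC", "CCCC", "CCCCC", "CC(C)", "CC(C)C",
    "c1ccc(cc1)", "Cc1ccc(cc1)", "COc1ccc(cc1)", "Fc1ccc(cc1)",
    "Clc1ccc(cc1)")
}

instantiate_template <- function(tpl, a, b) {
  fill <- function(s) gsub("{B}", b, gsub("{A}", a, s, fixed = TRUE), fixed = TRUE)
  paste(fill(tpl$left), fill(tpl$reagent), fill(tpl$right), sep = ">")
}

#' Generate synthetic template-class reactions
#'
#' Deterministically (seeded) instantiates `n_classes` reaction templates
#' with substituent pairs sampled without replacement from the pool grid, so
#' all reactions within a class are mutually distinct. Every generated
#' reaction passes [parse_reaction()] in strict mode; combinations the
#' backend rejects are skipped and replaced.
#'
#' @param n_classes number of template classes (at most the library size).
#' @param per_class reactions per class.
#' @param seed integer seed.
#' @param templates template library; default [reaction_templates()].
#' @param pool substituent pool; default [substituent_pool()].
#' @return a [labeled_reactions()] object with class labels (template names).
#' @examples
#' generate_template_reactions(2, 3, seed = 7)
#' @export
generate_template_reactions <- function(n_classes = 5, per_class = 100, seed = 1,
                                        templates = reaction_templates(),
                                        pool = substituent_pool()) {
  stopifnot(n_classes >= 1, per_class >= 1)
  if (n_classes > nrow(templates))
    drfp_error("drfp_pool_exhausted",
               sprintf("%d classes requested but only %d templates available",
                       n_classes, nrow(templates)))
  grid <- expand.grid(a = seq_along(pool), b = seq_along(pool))
  if (per_class > nrow(grid))
    drfp_error("drfp_pool_exhausted",
               sprintf("per_class = %d exceeds the %d distinct substituent pairs",
                       per_class, nrow(grid)))
  reactions <- character(0)
  labels <- character(0)
  with_seed(seed, {
    for (ci in seq_len(n_classes)) {
      tpl <- templates[ci, ]
      order_try <- sample.int(nrow(grid))
      got <- 0L
      for (gi in order_try) {
        rx <- instantiate_template(tpl, pool[grid$a[gi]], pool[grid$b[gi]])
        ok <- tryCatch({ parse_reaction(rx); TRUE },
                       drfp_error = function(e) FALSE)
        if (ok) {
          reactions <- c(reactions, rx)
          labels <- c(labels, tpl$name)
          got <- got + 1L
          if (got == per_class) break
        }
      }
      if (got < per_class)
        drfp_error("drfp_pool_exhausted",
                   sprintf("template '%s': only %d of %d valid instantiations",
                           tpl$name, got, per_class))
    }
  })
  labeled_reactions(reactions, labels, "class")
}

#' Attach rule-based synthetic yields to reactions
#'
#' Yields follow an additive structure-activity rule on the fragments the
#' fingerprint actually encodes: for each reaction the symmetric-difference
#' fragment set is computed, the effects of all map entries present in that
#' set are summed onto a base yield, seeded Gaussian noise is added, and the
#' result is clipped to `[0, 100]` percent. With `noise_sd = 0` the map from
#' structure to yield is exact.
#'
#' When `effect_map` is `NULL`, a default map is built from the data: up to
#' `n_effects` fragments with prevalence between 10% and 90% across the set
#' are drawn (seeded) and given effects uniform in +/-(10, 25) percentage
#' points, so that with the default `noise_sd = 5` the structural signal
#' dominates the noise (signal-to-noise ratio of roughly 4).
#'
#' @param x a [labeled_reactions()] object or character vector of reaction
#'   SMILES.
#' @param effect_map named numeric vector: fragment SMILES -> yield effect
#'   (percentage points), or `NULL` for the derived default.
#' @param noise_sd Gaussian noise standard deviation (percentage points).
#' @param seed integer seed.
#' @param base base yield (default 50).
#' @param n_effects number of fragments in the derived default map.
#' @param config fingerprint configuration used to compute fragment sets.
#' @return a [labeled_reactions()] object with yield labels; the effect map
#'   used is attached as attribute `"effect_map"`.
#' @export
generate_synthetic_yields <- function(x, effect_map = NULL, noise_sd = 5, seed = 1,
                                      base = 50, n_effects = 8,
                                      config = drfp_config()) {
  reactions <- if (inherits(x, "labeled_reactions")) x$reactions else as.character(x)
  stopifnot(noise_sd >= 0)
  frag_sets <- lapply(reactions, function(rx) {
    rec <- parse_reaction(rx)
    sides <- merge_sides(rec)
    shingling_difference(side_shingling(sides$left, config),
                         side_shingling(sides$right, config))
  })
  if (is.null(effect_map)) {
    all_frags <- unlist(frag_sets, use.names = FALSE)
    prev <- table(all_frags) / length(reactions)
    informative <- names(prev)[prev > 0.1 & prev < 0.9]
    if (length(informative) == 0)
      drfp_error("drfp_pool_exhausted",
                 "no fragments with intermediate prevalence; supply an effect_map")
    effect_map <- with_seed(seed + 1L, {
      chosen <- sample(informative, min(n_effects, length(informative)))
      effects <- runif(length(chosen), 10, 25) * sample(c(-1, 1), length(chosen), replace = TRUE)
      names(effects) <- chosen
      effects
    })
  }
  stopifnot(is.numeric(effect_map), length(effect_map) > 0, !is.null(names(effect_map)))
  signal <- vapply(frag_sets, function(fr)
    base + sum(effect_map[names(effect_map) %in% fr]), numeric(1))
  noise <- with_seed(seed, rnorm(length(reactions), 0, noise_sd))
  yields <- pmin(100, pmax(0, signal + noise))
  out <- labeled_reactions(reactions, yields, "yield")
  attr(out, "effect_map") <- effect_map
  out
}
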