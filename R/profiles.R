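# Packaged sandwich profiles: the typical (as-consumed) sandwich plus the
# five modeled composites. Nutrient values ship as an exact fixture; the
# food-pattern equivalents for the modeled sandwiches combine the composite
# design targets (grain 2 oz eq, meat 2.5 oz eq, cheese 1 cup eq, 0.1 cup
# dark-green + 0.1 cup red/orange vegetables) with package-constructed
# fatty-acid / solid-fat / added-sugar fields, stored in a file labelled
# _synthetic. The typical sandwich's equivalents are unknown and flagged.

#' Load the built-in sandwich profiles
#'
#' Returns the six packaged profiles: "Sandwich 0", the sandwich as
#' currently consumed in the typical US dietary pattern (the control), and
#' the five modeled composites — whole-grain or enriched-grain bread with
#' red meat or grilled chicken plus cheese and vegetables (1–4), and a soft
#' corn tortilla taco with chicken and cheese (5).
#'
#' Nutrient vectors come from the packaged fixture table. Food-pattern
#' equivalents for sandwiches 1–4 carry the composite targets; fatty-acid
#' grams, solid-fat energy and added-sugar teaspoons are package
#' assumptions (needed only to score modeled days with the HEI), and the
#' taco's equivalents are likewise assumed. Sandwich 0 has
#' `groups_known = FALSE` and an all-zero group vector: its food-pattern
#' content is not established, so pipelines score it from the recall data's
#' own item-level group fields, never from this profile.
#'
#' @return Named list of six [sandwich_profile()] objects, names
#'   `"Sandwich 0"` … `"Sandwich 5"`.
#' @export
#' @examples
#' p <- load_builtin_profiles()
#' p[["Sandwich 5"]]$nutrients[["energy"]]  # 264 kcal
load_builtin_profiles <- function() {
  nut_path <- system.file("extdata", "sandwich_profiles.csv",
                          package = "dietshift", mustWork = TRUE)
  grp_path <- system.file("extdata", "sandwich_profiles_groups_synthetic.csv",
                          package = "dietshift", mustWork = TRUE)
  nut <- utils::read.csv(nut_path, check.names = FALSE)
  grp <- utils::read.csv(grp_path, check.names = FALSE)
  stopifnot(identical(nut$name, grp$name))
  out <- vector("list", nrow(nut))
  names(out) <- nut$name
  for (i in seq_len(nrow(nut))) {
    nv <- nutrient_vector(unlist(nut[i, .NUTRIENTS]))
    gv <- foodgroup_vector(unlist(grp[i, .FOOD_GROUPS]))
    out[[i]] <- sandwich_profile(nut$name[i], nv, gv,
                                 groups_known = isTRUE(grp$groups_known[i]))
  }
  out
}
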