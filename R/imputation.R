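# Donor-based imputation for germplasm-bank species with missing pillar
# data. A recipient with an undetermined pillar takes values from a gene-pool
# donor (same crop group / genus) when one exists, otherwise from a
# provisional-crop-group donor (same FAO food category); among eligible
# donors the worst case -- the donor whose own data give the lowest decision
# index for that pillar -- is chosen to avoid inflating priority. Every
# pillar result carries an uncertainty tag: reliable (own data, or left
# undetermined), GP, or PCG. Vulnerability is never imputed, and species
# outside the bank (NCB group) are never imputed.

.pillar_vars <- list(
  geographic = "geographic",
  economic = c("lafay", "yield", "income", "coverage"),
  food_security = c("gov_list", "traditional", "nutrition", "affordability")
)

# fallback missingness flags when raw-data flags are not supplied: a label is
# treated as missing when it is undetermined
.missing_from_labels <- function(lab) {
  vars <- unlist(.pillar_vars, use.names = FALSE)
  out <- data.frame(species_id = lab$species_id, stringsAsFactors = FALSE)
  for (v in vars) out[[v]] <- lab[[v]] == "undetermined"
  out
}

#' Classify all pillars from a per-species label table
#'
#' @param lab `data.frame` with columns `species_id`, `geographic`,
#'   `vulnerability`, `lafay`, `yield`, `income`, `coverage`, `gov_list`,
#'   `traditional`, `nutrition`, `affordability` (labels; `undetermined`
#'   marks absent data; `gov_list` uses `not_included`/`included`).
#' @param cfg Run configuration.
#' @return `data.frame` with pillar labels and the two decision indices.
#' @export
classify_pillars <- function(lab, cfg = default_config()) {
  n <- nrow(lab)
  eco <- lapply(seq_len(n), function(i)
    classify_economic(unlist(lab[i, .pillar_vars$economic]), cfg))
  fs <- lapply(seq_len(n), function(i)
    classify_food_security(unlist(lab[i, .pillar_vars$food_security]), cfg))
  data.frame(
    species_id = lab$species_id,
    geographic = lab$geographic,
    vulnerability = lab$vulnerability,
    economic = vapply(eco, `[[`, character(1), "label"),
    food_security = vapply(fs, `[[`, character(1), "label"),
    economic_index = vapply(eco, `[[`, numeric(1), "decision_index"),
    food_index = vapply(fs, `[[`, numeric(1), "decision_index"),
    stringsAsFactors = FALSE
  )
}

.crop_group <- function(ids, species, cfg) {
  grp <- species$genus[match(ids, species$species_id)]
  if (length(cfg$crop_groups)) {
    hit <- ids %in% names(cfg$crop_groups)
    grp[hit] <- cfg$crop_groups[ids[hit]]
  }
  grp
}

.pillar_badness <- function(pil, pillar) {
  # lower = worse case; used to pick the most conservative donor
  if (pillar == "geographic")
    vapply(pil$geographic, ordinal_level, numeric(1), pillar = "geographic")
  else if (pillar == "economic") pil$economic_index
  else pil$food_index
}

#' Resolve an imputation donor for one species and pillar
#'
#' @param recipient Species id (must belong to the BGVCOL group for a donor
#'   to be searched).
#' @param lab Per-species label table (see [classify_pillars()]).
#' @param pil Pillar classification of `lab`.
#' @param species Species registry (`species_id`, `group`, `genus`,
#'   `fao_category`).
#' @param pillar `"geographic"`, `"economic"`, or `"food_security"`.
#' @param cfg Run configuration.
#' @param missing Optional logical data frame (same rows as `lab`, columns
#'   `species_id` plus the pillar variables) flagging variables whose raw
#'   data are absent; defaults to `label == "undetermined"`. A recipient is
#'   only imputed when its pillar classifies as undetermined *and* at least
#'   one of the pillar's variables has missing data: a species whose own data
#'   simply score too low to decide is left alone.
#' @return List with `recipient`, `donor` (id or `NA`), `path`
#'   (`"GP"`, `"PCG"`, `"none"`).
#' @export
resolve_donor <- function(recipient, lab, pil, species,
                          pillar = c("geographic", "economic",
                                     "food_security"),
                          cfg = default_config(), missing = NULL) {
  pillar <- match.arg(pillar)
  if (is.null(missing)) missing <- .missing_from_labels(lab)
  ri <- match(recipient, species$species_id)
  if (is.na(ri)) stop("unknown species id: ", recipient)
  none <- list(recipient = recipient, donor = NA_character_, path = "none")
  if (species$group[ri] != "BGVCOL") return(none)
  rp <- pil[pil$species_id == recipient, ]
  mi <- missing[missing$species_id == recipient, .pillar_vars[[pillar]],
                drop = FALSE]
  if (rp[[pillar]] != "undetermined" || !any(unlist(mi)))
    return(none)  # has data (or nothing to fill): no-op
  cand <- pil$species_id != recipient &
    species$group[match(pil$species_id, species$species_id)] == "BGVCOL" &
    pil[[pillar]] != "undetermined"
  if (!any(cand)) return(none)
  pick <- function(ids) {
    sub <- pil[pil$species_id %in% ids, ]
    bad <- .pillar_badness(sub, pillar)
    worst <- sub$species_id[bad == min(bad)]
    sort(worst)[1]
  }
  grp <- .crop_group(pil$species_id, species, cfg)
  gp <- cand & grp == grp[pil$species_id == recipient] & !is.na(grp)
  if (any(gp))
    return(list(recipient = recipient, donor = pick(pil$species_id[gp]),
                path = "GP"))
  fao <- species$fao_category[match(pil$species_id, species$species_id)]
  pcg <- cand & fao == fao[pil$species_id == recipient] & !is.na(fao)
  if (any(pcg))
    return(list(recipient = recipient, donor = pick(pil$species_id[pcg]),
                path = "PCG"))
  none
}

#' Apply donor imputation across a dataset
#'
#' For every bank-conserved species whose geographic, economic, or food
#' security pillar is undetermined, resolves a donor and copies the donor's
#' labels into the recipient's undetermined variables for that pillar
#' (labels already present are never overwritten; a variable the donor also
#' lacks stays undetermined). Pillars are then reclassified and tagged.
#'
#' @param lab Per-species label table.
#' @param species Species registry.
#' @param cfg Run configuration.
#' @param missing Optional per-variable missingness flags (see
#'   [resolve_donor()]).
#' @return List with `labels` (imputed label table), `pillars` (reclassified,
#'   with `tag_geographic`, `tag_economic`, `tag_food_security`), and `audit`
#'   (`data.frame`: recipient, pillar, donor, path, variables_filled).
#' @export
apply_imputation <- function(lab, species, cfg = default_config(),
                             missing = NULL) {
  if (is.null(missing)) missing <- .missing_from_labels(lab)
  # per-species geographic overrides (asserted origins) pre-empt imputation
  ov <- cfg$overrides$geographic
  if (length(ov)) {
    hit <- lab$species_id %in% names(ov)
    lab$geographic[hit] <- ov[lab$species_id[hit]]
  }
  pil <- classify_pillars(lab, cfg)
  audit <- list()
  tags <- matrix("reliable", nrow = nrow(lab), ncol = 3,
                 dimnames = list(NULL, names(.pillar_vars)))
  for (pillar in names(.pillar_vars)) {
    vars <- .pillar_vars[[pillar]]
    for (i in seq_len(nrow(lab))) {
      id <- lab$species_id[i]
      res <- resolve_donor(id, lab, pil, species, pillar, cfg, missing)
      if (res$path == "none") next
      di <- match(res$donor, lab$species_id)
      mrow <- missing[missing$species_id == id, , drop = FALSE]
      fill <- vars[vapply(vars, function(v)
        isTRUE(mrow[[v]][1]) && lab[[v]][i] == "undetermined", logical(1))]
      fill <- fill[vapply(fill, function(v)
        lab[[v]][di] != "undetermined", logical(1))]
      if (!length(fill)) next
      for (v in fill) lab[[v]][i] <- lab[[v]][di]
      tags[i, pillar] <- res$path
      audit[[length(audit) + 1L]] <- data.frame(
        recipient = id, pillar = pillar, donor = res$donor, path = res$path,
        variables_filled = paste(fill, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  pil <- classify_pillars(lab, cfg)
  pil$tag_geographic <- tags[, "geographic"]
  pil$tag_economic <- tags[, "economic"]
  pil$tag_food_security <- tags[, "food_security"]
  audit <- if (length(audit)) do.call(rbind, audit) else
    data.frame(recipient = character(0), pillar = character(0),
               donor = character(0), path = character(0),
               variables_filled = character(0), stringsAsFactors = FALSE)
  list(labels = lab, pillars = pil, audit = audit)
}
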