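#' Study design: arrays, gravity conditions and contrasts
#'
#' A study design maps each array to a campaign and a gravity condition and
#' carries the ordered list of condition contrasts tested for that campaign.
#' The two built-in campaigns mirror the flight platforms of gravitational
#' cell biology:
#'
#' * `PFC` (parabolic flight): conditions H/W (hardware ground control),
#'   1g (in-flight control), 1.8g (pull-up hypergravity), ug (microgravity);
#'   contrasts H/W vs 1g, 1g vs 1.8g, 1.8g vs ug, 1g vs ug.
#' * `TEXUS` (sounding rocket): conditions H/W, BL (post-launch baseline),
#'   ug; contrasts H/W vs BL, BL vs ug, H/W vs ug.
#'
#' @param arrays A data frame with columns `array_id`, `campaign`,
#'   `condition`.
#' @param conditions Ordered character vector of condition labels; defaults
#'   to the built-in order for known campaigns.
#' @param contrasts A data frame with columns `campaign`, `cond_a`, `cond_b`;
#'   defaults to the built-in contrasts for known campaigns.
#' @return A tibble of class `refstab_design` with attributes `conditions`
#'   and `contrasts`.
#' @export
study_design <- function(arrays, conditions = NULL, contrasts = NULL) {
  arrays <- tibble::as_tibble(arrays)
  stopifnot(all(c("array_id", "campaign", "condition") %in% names(arrays)))
  if (anyDuplicated(arrays$array_id)) {
    stop("duplicate array_id in design", call. = FALSE)
  }
  if (is.null(conditions)) {
    conditions <- unique(unlist(lapply(unique(arrays$campaign),
                                       campaign_conditions)))
  }
  if (!all(arrays$condition %in% conditions)) {
    bad <- setdiff(unique(arrays$condition), conditions)
    stop("unknown condition(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(contrasts)) {
    contrasts <- flight_contrasts()
    contrasts <- contrasts[contrasts$campaign %in% arrays$campaign, ]
  }
  contrasts <- tibble::as_tibble(contrasts)
  if (!all(c(contrasts$cond_a, contrasts$cond_b) %in% conditions)) {
    stop("contrasts reference undeclared conditions", call. = FALSE)
  }
  structure(arrays, class = c("refstab_design", class(tibble::tibble())),
            conditions = conditions, contrasts = contrasts)
}

#' @export
print.refstab_design <- function(x, ...) {
  cat(sprintf("# Study design: %d arrays, campaigns: %s\n", nrow(x),
              paste(unique(x$campaign), collapse = ", ")))
  NextMethod()
}

campaign_conditions <- function(campaign) {
  switch(campaign,
         PFC = c("H/W", "1g", "1.8g", "ug"),
         TEXUS = c("H/W", "BL", "ug"),
         stop("unknown campaign '", campaign,
              "'; supply `conditions` explicitly", call. = FALSE))
}

#' Condition contrasts tested per campaign
#'
#' The ordered pairwise comparisons applied to each gene, matching the
#' column layout of the per-campaign summary tables: four contrasts for the
#' parabolic flight campaign and three for the sounding rocket campaign.
#'
#' @return A tibble with columns `campaign`, `contrast`, `cond_a`, `cond_b`.
#' @export
flight_contrasts <- function() {
  tibble::tribble(
    ~campaign, ~cond_a, ~cond_b,
    "PFC",   "H/W",  "1g",
    "PFC",   "1g",   "1.8g",
    "PFC",   "1.8g", "ug",
    "PFC",   "1g",   "ug",
    "TEXUS", "H/W",  "BL",
    "TEXUS", "BL",   "ug",
    "TEXUS", "H/W",  "ug"
  ) |>
    dplyr::mutate(contrast = paste(.data$cond_a, "vs", .data$cond_b),
                  .after = "campaign")
}

#' Built-in flight study designs
#'
#' Array counts per condition follow the two flight campaigns: the parabolic
#' flight yielded 28 arrays (6 H/W, 8 1g, 6 1.8g, 8 ug) and the sounding
#' rocket 18 arrays (6 H/W, 5 BL, 7 ug).
#'
#' @param campaign `"PFC"` or `"TEXUS"`.
#' @return A `refstab_design` for the requested campaign.
#' @export
flight_design <- function(campaign = c("PFC", "TEXUS")) {
  campaign <- match.arg(campaign)
  counts <- switch(campaign,
                   PFC = c("H/W" = 6L, "1g" = 8L, "1.8g" = 6L, "ug" = 8L),
                   TEXUS = c("H/W" = 6L, "BL" = 5L, "ug" = 7L))
  arrays <- tibble::tibble(
    condition = rep(names(counts), counts),
    campaign = campaign
  )
  arrays$array_id <- sprintf("%s_%s_%02d", campaign,
                             gsub("[^A-Za-z0-9]", "", arrays$condition),
                             stats::ave(seq_len(nrow(arrays)),
                                        arrays$condition, FUN = seq_along))
  study_design(arrays[c("array_id", "campaign", "condition")])
}

design_conditions <- function(design) attr(design, "conditions")
design_contrasts <- function(design) attr(design, "contrasts")
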