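# Builds the field-study summary fixtures under inst/extdata/: the
# per-country, per-category intervention counts and mean category scores,
# the term-by-cost cross-tab, and the per-cycle antimicrobial-use counts of
# the three-country broiler cohort (13 NL, 7 CY, 15 GR farms, 4 cycles).
# The term/cost table's realized counts are reconstructed from the
# published whole-percent realization rates as round(n * pct / 100).
# Run from the package root: Rscript data-raw/build_fieldstudy.R

suppressPackageStartupMessages({
  library(tibble)
  library(dplyr)
  library(readr)
  library(tidyr)
})

# country, category, zone, planned, realized, mean category score
# (NL = Netherlands, CY = Cyprus, GR = Greece)
iv <- tribble(
  ~category_id, ~zone, ~nl_p, ~nl_r, ~nl_s, ~cy_p, ~cy_r, ~cy_s, ~gr_p, ~gr_r, ~gr_s,
  "g_purchased_animals", "green", 0, 0, 0.65, 7, 7, 0.66, 15, 0, 0.13,
  "g_bedding_materials", "green", 0, 0, 1.00, 0, 0, 1.00, 0, 0, 1.00,
  "g_contaminated_feed", "green", 0, 0, 0.98, 7, 0, 0.00, 15, 0, 0.50,
  "g_drinking_water", "green", 1, 1, 0.76, 21, 19, 0.68, 60, 30, 0.63,
  "g_thinning", "green", 2, 1, 0.14, 14, 0, 0.05, 45, 0, 0.00,
  "g_depopulation", "green", 0, 0, 0.18, 0, 0, 0.08, 0, 0, 0.00,
  "g_consecutive_flocks", "green", 2, 2, 0.85, 7, 2, 0.82, 15, 0, 0.58,
  "g_between_houses", "green", 3, 3, 0.57, 7, 0, 0.67, 15, 0, 0.87,
  "g_dead_bird_removal", "green", 5, 3, 0.64, 7, 1, 0.50, 0, 0, 1.00,
  "g_rodents_insects", "green", 2, 1, 0.93, 0, 0, 0.89, 0, 0, 1.00,
  "g_wild_birds", "green", 0, 0, 0.93, 7, 2, 0.29, 0, 0, 0.20,
  "g_outdoor_areas", "green", 0, 0, 0.42, 0, 0, 1.00, 0, 0, 0.60,
  "g_cd_entree_room", "green", 0, 0, 0.80, 0, 0, 0.35, 15, 15, 1.00,
  "g_cd_broiler_house", "green", 1, 1, 0.95, 0, 0, 1.00, 30, 0, 1.00,
  "og_personnel_visitors", "orange_green", 22, 19, 0.65, 35, 10, 0.21, 60, 45, 0.75,
  "og_materials", "orange_green", 0, 0, 0.51, 0, 0, 0.50, 0, 0, 0.12,
  "og_wild_birds_pests", "orange_green", 0, 0, 0.64, 0, 0, 0.72, 0, 0, 0.62,
  "o_house_position", "orange", 2, 2, 0.64, 7, 0, 1.00, 15, 0, 0.67,
  "o_cadaver_storage", "orange", 0, 0, 0.96, 0, 0, 0.50, 0, 0, 0.50,
  "o_manure_storage", "orange", 0, 0, 0.86, 0, 0, 1.00, 0, 0, 0.53,
  "o_feed_storage", "orange", 2, 2, 0.75, 7, 0, 0.50, 15, 0, 0.50,
  "o_bedding_storage", "orange", 1, 0, 0.79, 0, 0, 1.00, 15, 0, 0.00,
  "o_other_poultry", "orange", 0, 0, 0.89, 0, 0, 1.00, 0, 0, 0.75,
  "o_other_farm_animals", "orange", 0, 0, 0.63, 0, 0, 1.00, 0, 0, 0.72,
  "o_rodents_insects", "orange", 0, 0, 0.85, 0, 0, 0.67, 15, 0, 0.33,
  "o_wild_birds", "orange", 0, 0, 0.79, 0, 0, 0.72, 15, 0, 0.30,
  "o_yard_surfaces", "orange", 0, 0, 0.96, 0, 0, 0.71, 0, 0, 0.00,
  "o_cd_farm_yard", "orange", 2, 2, 0.68, 7, 0, 0.22, 1, 0, 0.49,
  "ro_personnel_visitors", "red_orange", 11, 7, 0.53, 7, 2, 0.53, 6, 0, 0.74,
  "ro_transport_vehicles", "red_orange", 4, 4, 0.38, 7, 2, 0.64, 15, 0, 0.02,
  "ro_wild_birds_pests", "red_orange", 2, 1, 0.74, 0, 0, 0.67, 0, 0, 0.64,
  "ro_fence_gate", "red_orange", 3, 2, 0.79, 7, 4, 0.57, 3, 0, 0.07,
  "ro_arrival_sign", "red_orange", 4, 2, 0.57, 0, 0, 0.71, 0, 0, 1.00,
  "ro_visitor_registration", "red_orange", 1, 1, 0.86, 7, 5, 0.00, 0, 0, 1.00,
  "r_poultry_density", "red", 0, 0, 0.79, 0, 0, 0.29, 0, 0, 0.13,
  "r_nearest_poultry_farm", "red", 0, 0, 0.64, 0, 0, 0.36, 2, 0, 0.43,
  "r_public_road", "red", 0, 0, 0.30, 0, 0, 0.57, 0, 0, 0.13,
  "r_poultry_litter_spread", "red", 0, 0, 0.80, 0, 0, 1.00, 1, 0, 0.56,
  "r_other_litter_spread", "red", 0, 0, 0.26, 0, 0, 0.04, 0, 0, 0.71,
  "r_mowing", "red", 1, 1, 0.23, 0, 0, 0.21, 0, 0, 0.50,
  "r_ploughing", "red", 0, 0, 0.45, 0, 0, 0.07, 0, 0, 0.50,
  "r_water_ponds", "red", 0, 0, 0.43, 0, 0, 0.57, 0, 0, 0.87,
  "r_migratory_route", "red", 0, 0, 0.71, 0, 0, 0.71, 0, 0, 0.93,
  "r_pest_pressure", "red", 0, 0, 0.75, 0, 0, 0.21, 0, 0, 0.00,
  "r_visitor_parking", "red", 4, 3, 0.43, 0, 0, 1.00, 0, 0, 1.00,
  "r_dirty_clean_separation", "red", 2, 1, 0.29, 7, 7, 0.48, 15, 0, 0.33
)

labels <- read_csv("inst/extdata/questionnaire.csv",
                   show_col_types = FALSE) |>
  distinct(category_id, category_label)

long <- bind_rows(
  iv |> transmute(country = "NL", zone, category_id,
                  n_planned = nl_p, n_realized = nl_r, mean_score = nl_s),
  iv |> transmute(country = "CY", zone, category_id,
                  n_planned = cy_p, n_realized = cy_r, mean_score = cy_s),
  iv |> transmute(country = "GR", zone, category_id,
                  n_planned = gr_p, n_realized = gr_r, mean_score = gr_s)
) |>
  left_join(labels, by = "category_id") |>
  select(country, zone, category_id, category_label, n_planned, n_realized,
         mean_score)

stopifnot(!any(is.na(long$category_label)))
# published zone totals: green 303, orange-green 117, orange 104,
# red-orange 77, red 32
check <- long |> group_by(zone) |> summarise(n = sum(n_planned))
stopifnot(identical(
  check$n[match(c("green", "orange_green", "orange", "red_orange", "red"),
                check$zone)],
  c(303, 117, 104, 77, 32)))
write_csv(long, "inst/extdata/fieldstudy_interventions.csv")

termcost <- tribble(
  ~term, ~cost, ~n_planned, ~pct_published,
  "short", "low", 222, 53,
  "short", "medium", 44, 43,
  "short", "high", 0, NA,
  "medium", "low", 88, 51,
  "medium", "medium", 94, 12,
  "medium", "high", 33, 21,
  "long", "low", 0, NA,
  "long", "medium", 44, 20,
  "long", "high", 111, 1
) |>
  mutate(n_realized = ifelse(n_planned > 0,
                             round(n_planned * pct_published / 100), 0L)) |>
  select(term, cost, n_planned, n_realized)
# the reconstructed counts must reproduce the published percents
chk <- round(100 * termcost$n_realized / termcost$n_planned)
stopifnot(identical(chk[termcost$n_planned > 0],
                    c(53, 43, 51, 12, 21, 20, 1)))
write_csv(termcost, "inst/extdata/fieldstudy_termcost.csv")

amu <- tribble(
  ~country, ~n_farms, ~cycle_index, ~n_farms_amu, ~median_days, ~mean_days,
  "NL", 13, 1, 3, 5, 5.3,
  "NL", 13, 2, 7, 3, 3.8,
  "NL", 13, 3, 8, 3, 3.5,
  "NL", 13, 4, 4, 4, 5.6,
  "CY", 7, 1, 6, 11, 10.7,
  "CY", 7, 2, 6, 4.5, 5.8,
  "CY", 7, 3, 3, 7, 6.0,
  "CY", 7, 4, 2, 6, 6.0,
  "GR", 15, 1, 15, 7, 6.4,
  "GR", 15, 2, 15, 5, 4.6,
  "GR", 15, 3, 15, 6, 6.0,
  "GR", 15, 4, 15, 6, 5.9
)
write_csv(amu, "inst/extdata/fieldstudy_amu.csv")
cat("field-study fixtures written\n")
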