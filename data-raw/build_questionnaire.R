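# Builds inst/extdata/questionnaire.csv: the packaged fixture instrument.
# The category list and zone assignment follow the published instrument's
# structure; the question texts are authored here (the original question
# list is not published), two questions per category, options scored 0 /
# 0.5 / 1 (a few binary 0/1).
# Run from the package root: Rscript data-raw/build_questionnaire.R

suppressPackageStartupMessages({
  library(tibble)
  library(dplyr)
  library(readr)
})

cat_tbl <- tribble(
  ~zone, ~category_id, ~label,
  "green", "g_purchased_animals", "Introduction of purchased animals",
  "green", "g_bedding_materials", "Introduction by bedding/enrichment materials",
  "green", "g_contaminated_feed", "Introduction by contaminated feed",
  "green", "g_drinking_water", "Introduction by drinking water",
  "green", "g_thinning", "Thinning",
  "green", "g_depopulation", "Depopulation",
  "green", "g_consecutive_flocks", "Spread of pathogens between consecutive flocks",
  "green", "g_between_houses", "Spread between farm broiler houses",
  "green", "g_dead_bird_removal", "Removal of dead birds from the house",
  "green", "g_rodents_insects", "Rodents/insects",
  "green", "g_wild_birds", "Wild birds",
  "green", "g_outdoor_areas", "Outdoor broiler areas",
  "green", "g_cd_entree_room", "Cleaning and disinfection of entree room",
  "green", "g_cd_broiler_house", "Cleaning and disinfection of broiler house",
  "orange_green", "og_personnel_visitors", "Access of personnel/visitors",
  "orange_green", "og_materials", "Access of materials",
  "orange_green", "og_wild_birds_pests", "Access of wild birds (and pest animals)",
  "orange", "o_house_position", "Position of broiler houses relative to internal-external logistic lines",
  "orange", "o_cadaver_storage", "Cadaver storage",
  "orange", "o_manure_storage", "Manure storage",
  "orange", "o_feed_storage", "Feed storage",
  "orange", "o_bedding_storage", "Storage of bedding materials",
  "orange", "o_other_poultry", "Other poultry species",
  "orange", "o_other_farm_animals", "Other farm animal species",
  "orange", "o_rodents_insects", "Rodents/insects",
  "orange", "o_wild_birds", "Wild birds",
  "orange", "o_yard_surfaces", "Contaminated farm yard surfaces",
  "orange", "o_cd_farm_yard", "Cleaning and disinfection of farm yard",
  "red_orange", "ro_personnel_visitors", "Access of personnel/visitors",
  "red_orange", "ro_transport_vehicles", "Access of transport vehicles",
  "red_orange", "ro_wild_birds_pests", "Access of wild birds (and pest animals)",
  "red_orange", "ro_fence_gate", "Separation orange and red zone by fence/wire and entrance gate",
  "red_orange", "ro_arrival_sign", "Arrival sign",
  "red_orange", "ro_visitor_registration", "Registration of visitors",
  "red", "r_poultry_density", "Poultry density in area",
  "red", "r_nearest_poultry_farm", "Distance to nearest poultry farm",
  "red", "r_public_road", "Shortest distance to public road with daily animal transports",
  "red", "r_poultry_litter_spread", "Spread of poultry litter/manure on surrounding fields",
  "red", "r_other_litter_spread", "Spread of other farm animal litter/manure on surrounding fields",
  "red", "r_mowing", "Mowing of premises",
  "red", "r_ploughing", "Ploughing in surrounding fields",
  "red", "r_water_ponds", "Water ponds present within radius of 1 km",
  "red", "r_migratory_route", "Migratory birds route in the vicinity within radius of 1 km",
  "red", "r_pest_pressure", "Pest animal pressure in surroundings",
  "red", "r_visitor_parking", "Parking areas visitors/farm employees in red zone",
  "red", "r_dirty_clean_separation", "Separation dirty-clean area: location of dirty road in red zone"
)

# Two authored questions per category. q1 asks about the preventive measure,
# q2 about its routine verification/hygiene aspect.
q_text <- list(
  g_purchased_animals = c(
    "Are incoming day-old chicks sourced from a single certified hatchery with health documentation?",
    "Are delivery crates and the delivery vehicle kept out of the broiler house?"),
  g_bedding_materials = c(
    "Is fresh bedding/enrichment material stored sealed and protected from birds and vermin until use?",
    "Is bedding obtained from a supplier with documented hygiene control?"),
  g_contaminated_feed = c(
    "Are feed silos and feed lines closed to wild birds, rodents and moisture?",
    "Is spilled feed removed the same day?"),
  g_drinking_water = c(
    "Is drinking water from a controlled source (mains or tested well) only?",
    "Are drinker lines cleaned and disinfected between flocks?"),
  g_thinning = c(
    "Does the thinning crew use farm-specific clothing, boots and crates?",
    "Are catching equipment and modules cleaned and disinfected before entering the house at thinning?"),
  g_depopulation = c(
    "Are final-catch crew and material hygiene rules enforced at depopulation?",
    "Is the house sealed against pest entry immediately after depopulation?"),
  g_consecutive_flocks = c(
    "Is a full dry-cleaning, washing and disinfection round completed between consecutive flocks?",
    "Is the sanitary empty period at least the agreed minimum days?"),
  g_between_houses = c(
    "Are house-specific boots and clothing used for each broiler house?",
    "Are tools and small equipment assigned per house rather than shared?"),
  g_dead_bird_removal = c(
    "Are dead birds collected from the house at least daily?",
    "Are carcasses moved out through a dedicated route that does not cross clean areas?"),
  g_rodents_insects = c(
    "Is a professional rodent and insect control programme active inside the house?",
    "Are bait points inside the house checked and logged at the agreed frequency?"),
  g_wild_birds = c(
    "Are all house openings (inlets, pop-holes, ridge) screened against wild birds?",
    "Is there a standing check that doors are never left open unattended?"),
  g_outdoor_areas = c(
    "Is the outdoor range fenced and netted to limit contact with wild birds?",
    "Is the outdoor area drained so standing water does not persist?"),
  g_cd_entree_room = c(
    "Does the entree room enforce a strict clean/dirty separation (bench or line) with hand hygiene?",
    "Is the entree room cleaned and disinfected after every flock?"),
  g_cd_broiler_house = c(
    "Is the broiler house cleaned and disinfected after every cycle following a written protocol?",
    "Is disinfection effectiveness verified (e.g., agar plates or ATP swabs)?"),
  og_personnel_visitors = c(
    "Do all persons entering the green zone change into farm boots and overalls?",
    "Do visitors sign in and respect the poultry-free waiting time before entry?"),
  og_materials = c(
    "Are materials entering the green zone disinfected or quarantined at the transition?",
    "Is there a hygiene lock (pass-through) for small materials?"),
  og_wild_birds_pests = c(
    "Is the orange-green transition protected against entry of wild birds and pest animals?",
    "Are doors at the transition self-closing and kept shut?"),
  o_house_position = c(
    "Are clean and dirty traffic lines on the yard physically separated?",
    "Do external vehicles avoid crossing the clean routes to the houses?"),
  o_cadaver_storage = c(
    "Are carcasses stored in a closed, cooled container at the yard edge?",
    "Is the cadaver container cleaned and disinfected after each collection?"),
  o_manure_storage = c(
    "Is manure stored covered and away from the broiler houses?",
    "Is manure removed from the yard without crossing clean routes?"),
  o_feed_storage = c(
    "Are feed silos intact, closed and inaccessible to birds and rodents?",
    "Is the area under and around the silos kept clean of spills?"),
  o_bedding_storage = c(
    "Is bedding stored indoors or sealed against moisture and vermin?",
    "Is stored bedding kept physically separated from manure and cadaver routes?"),
  o_other_poultry = c(
    "Is the farm free of other poultry species, or are they strictly separated from the broilers?",
    "Is any contact between broiler caretakers and other poultry avoided or managed with hygiene steps?"),
  o_other_farm_animals = c(
    "Are other farm animal species kept out of the orange zone?",
    "Are separate boots/clothing used when caring for other farm animals?"),
  o_rodents_insects = c(
    "Is a rodent control programme active on the farm yard?",
    "Is vegetation around the houses kept short to deny rodents cover?"),
  o_wild_birds = c(
    "Is the yard kept free of feed spills and standing water that attract wild birds?",
    "Are wild birds prevented from perching/nesting on the houses (deterrents, netting)?"),
  o_yard_surfaces = c(
    "Is the farm yard paved and drained so it can be cleaned?",
    "Are visibly contaminated yard spots cleaned without delay?"),
  o_cd_farm_yard = c(
    "Is the yard cleaned on a fixed schedule and after dirty transports?",
    "Is a disinfection step applied to the yard after high-risk events?"),
  ro_personnel_visitors = c(
    "Is entry from the public road onto the yard restricted to announced persons?",
    "Do drivers stay in their vehicle unless equipped with farm boots?"),
  ro_transport_vehicles = c(
    "Are external transport vehicles (feed, catching, rendering) kept at the red-orange boundary where possible?",
    "Are vehicle wheels/wheel arches disinfected at the entrance?"),
  ro_wild_birds_pests = c(
    "Is the red-orange boundary kept free of attractants (spills, open containers) for wild birds and pests?",
    "Are perimeter bait stations in place and maintained?"),
  ro_fence_gate = c(
    "Is the orange zone separated from the red zone by a continuous fence or wire?",
    "Is the entrance gate kept closed outside transport movements?"),
  ro_arrival_sign = c(
    "Is there a sign at the entrance instructing visitors to stop and report?",
    "Does the sign state the biosecurity rules (no entry, contact number)?"),
  ro_visitor_registration = c(
    "Is every visitor registered with date, name and previous poultry contact?",
    "Is the visitor log checked and retained for at least a year?"),
  r_poultry_density = c(
    "Is the farm located in an area of low poultry farm density?",
    "Is the number of poultry farms within 3 km known and monitored?"),
  r_nearest_poultry_farm = c(
    "Is the nearest other poultry farm more than 1 km away?",
    "Are there no shared facilities or staff with nearby poultry farms?"),
  r_public_road = c(
    "Is the farm entrance more than 500 m from a public road with daily animal transports?",
    "Is farm traffic routed to avoid roadside contamination being carried in?"),
  r_poultry_litter_spread = c(
    "Is poultry litter/manure spreading on fields adjoining the farm avoided?",
    "If spread nearby, is a buffer distance to the houses respected?"),
  r_other_litter_spread = c(
    "Is spreading of other species' manure on adjoining fields avoided?",
    "Are agreements in place with neighbours about manure spreading near the farm?"),
  r_mowing = c(
    "Are the premises mowed so grass stays short around the perimeter?",
    "Is mowing equipment used on the premises farm-own or cleaned before use?"),
  r_ploughing = c(
    "Is ploughing of surrounding fields timed/communicated to reduce dust and pest displacement toward the farm?",
    "Are field works near the houses avoided during sensitive periods?"),
  r_water_ponds = c(
    "Is the farm free of open water ponds within 1 km?",
    "If ponds are present, are waterfowl deterred near the farm?"),
  r_migratory_route = c(
    "Is the farm outside known migratory waterbird routes or resting sites within 1 km?",
    "Is heightened vigilance applied during migration seasons?"),
  r_pest_pressure = c(
    "Is pest animal pressure in the surroundings low or actively managed?",
    "Is the perimeter checked for pest activity on a schedule?"),
  r_visitor_parking = c(
    "Is visitor and employee parking located in the red zone away from farm traffic lines?",
    "Is the parking area separated from the yard by the fence/gate?"),
  r_dirty_clean_separation = c(
    "Is the dirty road (rendering, manure) located in the red zone, separate from the clean entrance?",
    "Do dirty and clean routes avoid any crossing point?")
)

stopifnot(setequal(names(q_text), cat_tbl$category_id))

graded_opts <- tibble(
  option_id = c("a", "b", "c"),
  option_text = c("yes, fully", "partly", "no"),
  points = c(1, 0.5, 0)
)
binary_opts <- tibble(
  option_id = c("a", "b"),
  option_text = c("yes", "no"),
  points = c(1, 0)
)
# second questions about presence/absence are binary; first are graded
rows <- list()
for (i in seq_len(nrow(cat_tbl))) {
  cid <- cat_tbl$category_id[i]
  for (j in 1:2) {
    opts <- if (j == 2 && i %% 2 == 0) binary_opts else graded_opts
    rows[[length(rows) + 1L]] <- tibble(
      zone = cat_tbl$zone[i],
      category_id = cid,
      category_label = cat_tbl$label[i],
      question_id = sprintf("%s_q%d", cid, j),
      question_text = q_text[[cid]][j],
      option_id = opts$option_id,
      option_text = opts$option_text,
      points = opts$points,
      allow_na = TRUE
    )
  }
}
out <- bind_rows(rows)
write_csv(out, "inst/extdata/questionnaire.csv")
cat("wrote", nrow(out), "option rows for", nrow(cat_tbl), "categories\n")
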