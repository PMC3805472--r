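#' Default item catalog for the episodic choice task
#'
#' Thirty concrete reward items, ten per domain (food, culture, sport),
#' each with an ordinal price tier 1--10 (tiers increase with the nominal
#' price of the item, all in the 1--100 euro range). The delayed option of
#' a trial is always the higher-tier (more desirable) of the two drawn
#' items, so that choices oppose a less pleasant immediate option to a
#' more pleasant delayed one.
#'
#' @return a data.frame with columns `domain`, `item`, `tier`.
#' @examples
#' table(default_item_catalog()$domain)
#' @export
default_item_catalog <- function() {
  sport <- c(
    "A free bowling session in a bar",
    "A hiking session in Fontainebleau",
    "One hour of body massage",
    "An initiation to Aikido practice",
    "An indoor climbing session in Bercy",
    "A rowing session on Cergy lake",
    "A seat for a premier league rugby game",
    "A seat for a first league football game",
    "A horse riding tour in the Bois de Vincennes",
    "A seat for the Roland Garros tennis tournament final"
  )
  culture <- c(
    "A visit of the Menagerie du Jardin des Plantes",
    "A visit of the Palais de la Decouverte",
    "A 1-hour chess lesson",
    "A guided tour of Centre Pompidou",
    "A guided tour of the Musee du Louvre",
    "A day at the Chateau de Versailles",
    "A salsa dancing lesson",
    "A 2-h oenology lesson",
    "A theater play at the Comedie Francaise",
    "A concert in a Paris Jazz Club"
  )
  food <- c(
    "A packet of crisps",
    "A piece of cheesecake",
    "A glass of red wine",
    "A cup of Champagne",
    "A lunch in Italian pizzeria",
    "A Japanese meal in front of Notre-Dame cathedral",
    "A diner on a Paris river boat",
    "A plate of seafood on the Champs-Elysees",
    "A breakfast at the Tour Eiffel restaurant",
    "A lobster in the Tour Montparnasse restaurant"
  )
  out <- data.frame(
    domain = rep(c("food", "culture", "sport"), each = 10L),
    item = c(food, culture, sport),
    tier = rep(1:10, times = 3L),
    stringsAsFactors = FALSE
  )
  validate_catalog(out)
  out
}

## Catalog sanity: required columns, unique labels within domain.
validate_catalog <- function(catalog) {
  stopifnot(is.data.frame(catalog),
            all(c("domain", "item", "tier") %in% names(catalog)))
  dup <- tapply(catalog$item, catalog$domain, function(x) any(duplicated(x)))
  if (any(dup)) {
    stop("duplicated item labels within domain(s): ",
         paste(names(dup)[dup], collapse = ", "))
  }
  invisible(catalog)
}
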