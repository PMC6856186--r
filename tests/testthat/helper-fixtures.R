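# Fixtures built in code: a three-country trading world with hand-checked
# fluxes, and small writers for the tabular readers.

# Countries A, B, C. A exports 30 Mg to B and 10 Mg to C; B exports 10 Mg
# to A. Sheets close exactly. Concentrations (ng/g): THg A=10, B=20, C=5;
# MeHg A=2, B=4, C=1.
three_country_sheets <- function() {
  tibble::tibble(
    country = c("A", "B", "C"), year = 2013L,
    production = c(100, 200, 0),
    import = c(10, 30, 10),
    stock_variation = c(0, 5, 0),
    export = c(40, 10, 0),
    feed = c(7, 20, 0),
    seed = c(3, 10, 0),
    processing = c(2, 8, 0),
    other_uses = c(1, 4, 0),
    food = c(56, 180, 10),
    losses = c(1, 3, 0)
  )
}

three_country_trade <- function() {
  tibble::tibble(
    reporter = c("A", "A", "B"),
    partner = c("B", "C", "A"),
    quantity_Mg = c(30, 10, 10)
  )
}

three_country_conc <- function() {
  tibble::tibble(
    country = c("A", "B", "C"),
    thg_ng_g = c(10, 20, 5),
    mehg_ng_g = c(2, 4, 1)
  )
}

write_sheets_csv <- function(sheets, path = tempfile(fileext = ".csv")) {
  write_balance_sheets(sheets, path)
  path
}

# Minimal valid concentration-record row, overridable field by field.
make_record <- function(record_id = "R1", country = "A", lat = 0, lon = 0,
                        site_class = "background", organ = "grain",
                        species = "THg", median_ng_g = 10, gsd = 1.5,
                        n = 10L, year = 2013L) {
  tibble::tibble(record_id = record_id, country = country, lat = lat,
                 lon = lon, site_class = site_class, organ = organ,
                 species = species, median_ng_g = median_ng_g, gsd = gsd,
                 n = n, year = year)
}
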