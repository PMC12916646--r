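# Shared fixtures, all built in code at test time.

# a small synthetic database with strong injected signals, cached per session
small_db <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- srs_config(
        n_reports = 4000, target_share = 0.08, duplicate_rate = 0.05,
        injected_signals = data.frame(
          pt = c("Haematemesis", "Skin necrosis", "PT_0030"),
          rr = c(10, 8, 12)),
        seed = 2024)
      cache <<- generate_srs(cfg)
    }
    cache
  }
})

# hand-built database: 4 reports, 2 exposed to the target drug
# r1: {ptX}, r2: {ptX, ptY} (target); r3: {ptX}, r4: {ptZ} (background)
toy_db <- function() {
  demo <- data.frame(
    primaryid = c("1", "2", "3", "4"), caseid = c("c1", "c2", "c3", "c4"),
    fda_dt = "20230110", event_dt = "20230105", age = c("60", "70", "", "30"),
    age_cod = c("YR", "YR", "", "YR"), sex = c("F", "M", "F", ""),
    occp_cod = c("MD", "CN", "MD", ""), occr_country = "US",
    stringsAsFactors = FALSE)
  drug <- data.frame(
    primaryid = c("1", "2", "3", "4", "4"),
    drug_seq = c("1", "1", "1", "1", "2"),
    role_cod = c("PS", "PS", "PS", "PS", "C"),
    drugname = c("ARIXTRA", "Fondaparinux  sodium", "DRUG_001", "DRUG_002",
                 "ASPIRIN"),
    stringsAsFactors = FALSE)
  reac <- data.frame(
    primaryid = c("1", "2", "2", "3", "4"),
    pt = c("ptX", "ptX", "ptY", "ptX", "ptZ"),
    stringsAsFactors = FALSE)
  ther <- data.frame(primaryid = c("1", "2"), dsg_drug_seq = c("1", "1"),
                     start_dt = "20230101", stringsAsFactors = FALSE)
  srs_data(demo, drug, reac, ther)
}

toy_pt_soc <- function() {
  data.frame(pt = c("ptX", "ptY", "ptZ"),
             soc = c("SOC A", "SOC A", "SOC B"),
             stringsAsFactors = FALSE)
}

toy_tables <- function() {
  tab <- build_event_table(toy_db(), toy_pt_soc())
  build_contingency(tab$reports, tab$events, "pt")
}
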