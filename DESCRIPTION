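Package: evworkload
Title: Equivalent-Value Workload Model for Village Doctors in China's
    Essential Public Health Services Program
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the equivalent-value (EV) model for measuring the
    share of China's National Essential Public Health Services (NEPHS)
    workload delivered by village doctors. Every service item is weighted by
    its person-minutes relative to a 15-minute standard clinic visit (EV = 1);
    township hospital center (THC) survey records of annual service volumes
    and village-doctor delegation fractions are aggregated into total EVs
    (Y), village-doctor EVs (X) and percentage shares X/Y at any scope
    (item, service type, THC, province, overall), with a 40-percent policy
    compliance check. Ships the built-in two-region EV catalog (38 items in
    12 service types), survey readers/writers with validation, a seedable
    hierarchical synthetic-survey generator emulating a stratified sampling
    frame (6 provinces x 5 prefectures x 2 counties x 5 THCs), and report
    renderers for by-type and by-province share tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    readr,
    tibble,
    rlang,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
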