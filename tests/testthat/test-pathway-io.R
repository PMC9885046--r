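test_that("KGML parsing extracts reactions, shared compounds and reversibility", {
  f <- write_tmp_kgml(c(
    kgml_reaction("R00001", "C00010", "C00099"),
    kgml_reaction("R00002", "C00099", "C00012", reversible = TRUE)))
  pw <- parse_kgml(f)
  expect_s3_class(pw, "pathway")
  expect_equal(pw$id, "map99999")
  expect_length(pw$reactions, 2)
  expect_equal(pw$reactions$R00001$products, "C00099")
  expect_equal(pw$reactions$R00002$substrates, "C00099")
  expect_false(pw$reactions$R00001$reversible)
  expect_true(pw$reactions$R00002$reversible)
})

test_that("KGML with no reaction entries gives an empty pathway", {
  pw <- parse_kgml(write_tmp_kgml(character()))
  expect_length(pw$reactions, 0)
})

test_that("KGML reaction entries lacking one side are skipped with a warning", {
  f <- write_tmp_kgml(c(
    kgml_reaction("R00001", "C00010", "C00011"),
    '<reaction id="0" name="rn:R00002" type="irreversible"><substrate id="0" name="cpd:C00011"/></reaction>'))
  expect_warning(pw <- parse_kgml(f), "lacks substrates or products")
  expect_equal(names(pw$reactions), "R00001")
})

test_that("malformed XML is a parse error", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines("<pathway><reaction>", f)
  expect_error(parse_kgml(f))
})

test_that("the synthetic focal-pathway KGML fixture yields the 15-reaction common core", {
  f <- system.file("extdata", "ttp_synthetic.kgml", package = "pathcontext")
  pw <- parse_kgml(f)
  expect_setequal(names(pw$reactions),
                  c("R02412", "R03460", "R01373", "R01714", "R01715",
                    "R00674", "R02722", "R02340", "R03508", "R03509",
                    "R01073", "R00985", "R00986", "R03084", "R02413"))
  secs <- read_section_map(system.file("extdata", "ttp_sections.tsv",
                                       package = "pathcontext"))
  expect_setequal(names(secs), names(pw$reactions))
  expect_setequal(unique(secs), c("Input", "Shikimate", "Tryptophan", "PheTyr"))
})

test_that("reaction tables map fields directly and reject bad input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tsubstrates\tproducts\treversible\tpathway_id",
               "R1\tA;B\tC\t0\tmapX"), f)
  pw <- parse_reaction_table(f)
  expect_length(pw$reactions, 1)
  expect_setequal(pw$reactions$R1$substrates, c("A", "B"))
  expect_equal(pw$reactions$R1$products, "C")
  expect_false(pw$reactions$R1$reversible)
  expect_equal(pw$id, "mapX")

  writeLines(c("reaction_id\tsubstrates\tproducts\treversible\tpathway_id",
               "R1\tA\tB\t0\tmapX", "R1\tA\tC\t0\tmapX"), f)
  expect_error(parse_reaction_table(f), "duplicate")
  writeLines(c("reaction_id\tsubstrates\tproducts\treversible\tpathway_id",
               "R1\tA\tB\tyes\tmapX"), f)
  expect_error(parse_reaction_table(f), "reversibility")
})

test_that("pathway -> TSV -> pathway round trip is the identity", {
  pw <- pathway("mapZ", "fixture", list(
    reaction("R1", c("A", "B"), "C", reversible = TRUE),
    reaction("R2", "C", c("D", "E")),
    reaction("R3", "E", "A")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_reaction_table(pw, f)
  pw2 <- parse_reaction_table(f)
  expect_equal(pw2$id, pw$id)
  expect_equal(names(pw2$reactions), names(pw$reactions))
  for (id in names(pw$reactions)) {
    expect_setequal(pw2$reactions[[id]]$substrates, pw$reactions[[id]]$substrates)
    expect_setequal(pw2$reactions[[id]]$products, pw$reactions[[id]]$products)
    expect_identical(pw2$reactions[[id]]$reversible, pw$reactions[[id]]$reversible)
  }
})

test_that("TSV and KGML encodings of the same chain parse to the same pathway", {
  kf <- write_tmp_kgml(c(kgml_reaction("R1", "A", "B"),
                         kgml_reaction("R2", "B", "C", reversible = TRUE),
                         kgml_reaction("R3", "C", "D")), pid = "mapQ")
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tsubstrates\tproducts\treversible\tpathway_id",
               "R1\tA\tB\t0\tmapQ", "R2\tB\tC\t1\tmapQ", "R3\tC\tD\t0\tmapQ"),
             tf)
  a <- parse_kgml(kf); b <- parse_reaction_table(tf)
  expect_equal(names(a$reactions), names(b$reactions))
  for (id in names(a$reactions)) {
    expect_equal(a$reactions[[id]]$substrates, b$reactions[[id]]$substrates)
    expect_equal(a$reactions[[id]]$products, b$reactions[[id]]$products)
    expect_equal(a$reactions[[id]]$reversible, b$reactions[[id]]$reversible)
  }
  # and they induce identical networks
  na <- build_reaction_network(a, character())
  nb <- build_reaction_network(b, character())
  expect_equal(na$edges, nb$edges)
})

test_that("section maps reject multi-section reactions and unknown labels", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tsection", "R1\tInput", "R1\tShikimate"), f)
  expect_error(read_section_map(f), "more than one section")
  writeLines(c("reaction_id\tsection", "R1\tNotASection"), f)
  expect_error(read_section_map(f), "unknown section")
})

test_that("id maps are pure lookups and idempotent on their output", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("from\tto", "S001_01\tT01", "S001_02\tRP1"), f)
  map <- read_id_map(f)
  once <- apply_id_map(c("S001_01", "S001_02", "UNMAPPED"), map)
  expect_equal(once, c("T01", "RP1", "UNMAPPED"))
  expect_equal(apply_id_map(once, map), once)
})

test_that("edge lists are written one tab-separated directed edge per line", {
  pw <- chain_pathway(mets = c("A", "B", "C"), reversible = c(TRUE, TRUE))
  net <- build_reaction_network(pw, character())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, f)
  lines <- readLines(f)
  expect_setequal(lines, c("R1\tR2", "R2\tR1"))
})
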