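test_that("compound CSV round-trips and rejects malformed input", {
  tab <- tiny_compound_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_compound_csv(tab, path)
  back <- read_compound_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))

  nd <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,replicate,compound,value",
               "H-C-JH,1,GMP,ND", "H-C-JH,1,IMP,2.75"), nd)
  got <- read_compound_csv(nd)
  expect_false(got$detected[got$compound == "GMP"])
  expect_equal(got$value[got$compound == "GMP"], 0)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,replicate,compound,value", "M-C-JH,1,Glu,-1.0"), bad)
  expect_error(read_compound_csv(bad), "negative")
  writeLines(c("sample,replicate,compound", "M-C-JH,1,Glu"), bad)
  expect_error(read_compound_csv(bad), "missing column")
  writeLines(c("sample,replicate,compound,value", "M-C-CJ,1,Glu,1"), bad)
  expect_error(read_compound_csv(bad), "unknown sample")
  writeLines(c("sample,replicate,compound,value", "M-C-JH,1,Foo,1"), bad)
  expect_error(read_compound_csv(bad), "unknown compound")
})

test_that("sample keys parse only the nine-sample design", {
  expect_length(crab_samples(), 9)
  parsed <- parse_sample_key(crab_samples())
  expect_equal(parsed$sample, crab_samples())
  expect_equal(sum(parsed$origin == "C"), 3)  # Chongming reared only JH
  expect_true(all(parsed$variety[parsed$origin == "C"] == "JH"))
  expect_error(parse_sample_key("M-C-CJ"), "unknown sample")
  expect_error(parse_sample_key("X-T-JH"), "unknown sample")
})

test_that("replicate summaries use the n-1 sample SD", {
  one <- compound_table(data.frame(sample = "M-C-JH", replicate = 1,
                                   compound = "Asp", value = 7.12))
  s <- summarize_replicates(one)
  expect_equal(s$mean, 7.12)
  expect_equal(s$sd, 0)
  expect_equal(s$n, 1L)

  s2 <- summarize_replicates(tiny_compound_table())
  glu <- s2[s2$compound == "Glu", ]
  expect_equal(glu$mean, 7)
  expect_equal(glu$sd, sqrt(2))
  expect_equal(glu$n, 2L)
})

test_that("summaries of regenerated replicates recover the source moments", {
  src <- load_crab_compounds()
  tab <- gen_compound_replicates(src, n = 3, seed = 101)
  s <- summarize_replicates(tab)
  key <- paste(s$sample, s$compound)
  idx <- match(paste(src$sample, src$compound), key)
  # each cell mean within 3 SD of the generating mean; sd = 0 cells exact
  expect_true(all(abs(s$mean[idx] - src$mean) <= 3 * src$sd + 1e-12))
  exact <- src$sd == 0
  expect_equal(s$mean[idx][exact], src$mean[exact])
})

test_that("category sums reproduce the published summary rows", {
  s <- load_crab_compounds()
  expect_equal(category_sum(s, "umami", "M-C-JH"), 73.24, tolerance = 1e-9)
  expect_equal(category_sum(s, "sweet", "H-C-JH"), 797.18,
               tolerance = 0.05 / 797.18)
  expect_equal(category_sum(s, "total", "M-C-JH"), 2435.35,
               tolerance = 0.05 / 2435.35)
  for (row in c("UFAA", "SFAA", "BFAA", "FAA")) {
    cat <- c(UFAA = "umami", SFAA = "sweet", BFAA = "bitter",
             FAA = "total")[[row]]
    got <- vapply(crab_samples(), function(sm) category_sum(s, cat, sm), 1)
    expect_true(all(abs(got - printed_row(row)) <= 0.05),
                label = paste("printed", row, "reconstruction"))
  }
})

test_that("category sums are additive and partition the FAA total", {
  s <- load_crab_compounds()
  for (sm in crab_samples()) {
    parts <- vapply(c("umami", "sweet", "bitter", "uncategorized"),
                    function(ct) category_sum(s, ct, sm), 1)
    expect_equal(sum(parts), category_sum(s, "total", sm),
                 tolerance = 1e-9)
  }
  # empty category sums to zero
  glu_only <- sample_summary(data.frame(sample = "M-C-JH", compound = "Glu",
                                        mean = 5, sd = 0))
  expect_equal(category_sum(glu_only, "uncategorized", "M-C-JH"), 0)
  expect_error(category_sum(s, "savoury", "M-C-JH"), "unknown category")
  # splitting a category into two disjoint halves leaves the sum unchanged
  sweet <- faa_categories("table")$sweet
  halves <- list(sweet[1:3], sweet[4:6])
  split_sum <- sum(vapply(halves, function(h)
    sum(s$mean[s$sample == "M-T-JH" & s$compound %in% h]), 1))
  expect_equal(split_sum, category_sum(s, "sweet", "M-T-JH"))
})

test_that("the two category schemes differ exactly by Met and Arg", {
  tab <- faa_categories("table")
  txt <- faa_categories("text")
  expect_setequal(setdiff(txt$bitter, tab$bitter), "Met")
  expect_setequal(setdiff(tab$sweet, txt$sweet), "Arg")
  for (sch in list(tab, txt)) {
    expect_length(unlist(sch), length(unique(unlist(sch))))  # disjoint
    voc <- compound_vocabulary()
    expect_true(all(unlist(sch) %in% voc$compound[voc$class == "faa"]))
  }
})
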