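test_that("canonical query forms parse to the expected ASTs", {
  q <- parse_query("cui:C0019196 cui:C0019158")
  expect_length(q$nodes, 2L)
  expect_identical(q$nodes[[1]]$layer, "cui")
  expect_identical(q$nodes[[2]]$value, "C0019158")
  expect_identical(q$nodes[[1]]$weight, 1)

  p <- parse_query("#p(8|true|coinfected|hepatitis)^0.1")$nodes[[1]]
  expect_identical(p$type, "phrase")
  expect_identical(p$window, 8L)
  expect_true(p$ordered)
  expect_identical(p$weight, 0.1)
  expect_identical(p$components[[1]]$layer, "text")
  expect_identical(p$components[[2]]$value, "hepatitis")

  # whitespace is tolerated after the separator
  l <- parse_query("#l(cui:C0019158| hepatitis)")$nodes[[1]]
  expect_identical(l$type, "list")
  expect_identical(l$members[[1]]$layer, "cui")
  expect_identical(l$members[[2]]$layer, "text")
  expect_identical(l$members[[2]]$value, "hepatitis")

  r <- parse_query("#r(dep|lemma:give|pos:NNP)")$nodes[[1]]
  expect_identical(r$type, "relation")
  expect_identical(r$layer, "dep")
  expect_identical(r$label, "*")
  expect_identical(r$source$layer, "lemma")
  expect_identical(r$target$value, "NNP")
  r2 <- parse_query("#r(dep:nsubj|*|*)")$nodes[[1]]
  expect_identical(r2$label, "nsubj")
  expect_identical(r2$source, "*")
})

test_that("malformed queries fail with positioned errors", {
  expect_error(parse_query("#p(8|true|onlyone)"), "at least 2")
  expect_error(parse_query("#p(0|true|a|b)"), "window")
  expect_error(parse_query("#p(8|maybe|a|b)"), "true or false")
  expect_error(parse_query("#l(a|b"), "expected")
  expect_error(parse_query("a^0"), "positive")
  expect_error(parse_query("a^-2"), "positive")
  expect_error(parse_query("   "), "empty query")
})

test_that("render is the left inverse of parse and vice versa", {
  strings <- c(
    "coinfected hepatitis c hiv",
    "cui:C0019196 cui:C0019158",
    "coinfected #l(cui:C0019158|hepatitis) hiv",
    "#p(8|true|coinfected|hepatitis)^0.1 #p(8|false|coinfected|hepatitis)^0.05",
    "#p(12|true|coinfected|cui:C0019158|hiv)^0.1",
    "#r(dep|lemma:give|pos:NNP) plavix",
    "#p(8|true|coinfected|#l(cui:C0019158|hepatitis))^0.1"
  )
  for (s in strings) {
    expect_identical(render_query(parse_query(s)), s)
  }
  set.seed(1001)
  for (rep in 1:100) {
    q <- new_query_for_test(lapply(seq_len(sample(1:4, 1)),
                                   function(i) random_ast_node()))
    expect_identical(parse_query(render_query(q)), q)
  }
})

test_that("sdm_expand reproduces the canonical two-concept expansion", {
  q <- sdm_expand("cui:C0019196 cui:C0019158")
  expect_identical(
    render_query(q),
    paste("cui:C0019196^0.85 cui:C0019158^0.85",
          "#p(8|true|cui:C0019196|cui:C0019158)^0.1",
          "#p(8|false|cui:C0019196|cui:C0019158)^0.05"))
})

test_that("sdm_expand emits all subsequence phrases with 4k windows", {
  q <- sdm_expand("coinfected hepatitis c hiv")
  types <- vapply(q$nodes, `[[`, character(1), "type")
  expect_identical(sum(types == "term"), 4L)
  phrases <- q$nodes[types == "phrase"]
  ks <- vapply(phrases, function(p) length(p$components), integer(1))
  ws <- vapply(phrases, `[[`, integer(1), "window")
  os <- vapply(phrases, `[[`, logical(1), "ordered")
  wt <- vapply(phrases, `[[`, numeric(1), "weight")
  expect_identical(as.integer(table(ks)), c(6L, 4L, 2L))
  expect_true(all(ws == 4L * ks))
  expect_identical(unique(wt[os]), 0.1)
  expect_identical(unique(wt[!os]), 0.05)
  expect_true(all(vapply(q$nodes[types == "term"], `[[`, numeric(1),
                         "weight") == 0.85))
})

test_that("sdm_expand caps phrase length and follows the closed-form count", {
  count_for <- function(n, cap = 5L) {
    n + 2L * sum(pmax(n - (2:min(n, cap)) + 1L, 0L) *
                   (2:min(n, cap) <= n))
  }
  for (n in 1:8) {
    atoms <- lapply(seq_len(n), function(i) term_node("text", letters[i]))
    q <- sdm_expand(atoms)
    expected <- if (n == 1) 1L else count_for(n)
    expect_length(q$nodes, expected)
    ks <- vapply(q$nodes, function(x) {
      if (x$type == "phrase") length(x$components) else 1L
    }, integer(1))
    expect_lte(max(ks), 5L)
  }
  # lists are legal atoms; bare phrases are not
  lst <- parse_query("#l(cui:C0019158|hepatitis)")$nodes[[1]]
  q <- sdm_expand(list(term_node("text", "coinfected"), lst))
  expect_identical(render_query(q$nodes[[4]]),
                   "#p(8|false|coinfected|#l(cui:C0019158|hepatitis))^0.05")
  ph <- parse_query("#p(8|true|a|b)")$nodes[[1]]
  expect_error(sdm_expand(list(ph)), "term or list")
  expect_error(sdm_expand(list()), "at least one atom")
})

test_that("sdm constants are configurable", {
  q <- sdm_expand("a b", sdm_config(lambda_term = 0.9,
                                    lambda_ordered = 0.07,
                                    lambda_unordered = 0.03,
                                    window_per_component = 2L))
  expect_identical(render_query(q),
                   "a^0.9 b^0.9 #p(4|true|a|b)^0.07 #p(4|false|a|b)^0.03")
})
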