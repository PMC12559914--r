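Package: fidplan
Title: Fiducial Marker Placement Planning for CyberKnife Stereotactic
    Body Radiotherapy of Superficial Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans gold fiducial marker implantation sites for CyberKnife
    stereotactic body radiotherapy (SBRT) of superficial tumors (roughly
    20-50 mm beneath the epidermis). A tensor-product B-spline surface is
    least-squares fitted to a point cloud surrounding the tumor, uniformly
    sampled into candidate implantation sites, and candidate triples are
    selected under the clinical tracking constraints: inter-marker distance
    of at least 18 mm, triangle angles of at least 30 degrees, marker to
    tumor-centroid distance of at most 50 mm, and non-overlapping marker
    projections in the two 45-degree oblique kV imaging views. The search
    uses a kd-tree fixed-radius query to build the admissible-distance
    graph and clique enumeration to extract valid marker sets, with an
    exhaustive brute-force planner retained as a correctness oracle.
    Includes a synthetic ellipsoidal phantom generator, a 10-point plan
    scoring rubric, JSON/CSV/Markdown reporting, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
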