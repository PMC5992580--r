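# Curated per-proband PALB2 variant reports from published hereditary diffuse
# gastric cancer sequencing studies (CDH1-negative probands), one row per
# reported variant. 329 probands were screened across the contributing
# studies; that denominator is supplied by the caller, not stored here.
# The `excluded` column carries the compilation's bookkeeping:
#   search_criteria — unpublished collaborator report outside the literature
#     search window, kept for completeness but never counted;
#   intestinal_type — proband with intestinal-type (not diffuse) gastric
#     cancer; flagged so the counted carrier set matches the published total
#     of 5 loss-of-function carriers (the published count is one fewer than
#     the nominally loss-of-function rows, and the intestinal-type diagnosis
#     is the one reported inclusion mismatch).
study	patient_id	gene	variant	consequence	population	diagnosis	excluded
hansford_2015	P124	PALB2	c.1193AC>A	fs deletion	European	Diffuse gastric cancer (45)	
sahasrabudhe_2017	CG-12	PALB2	c.1240C>T	Stop-site gain	European	Intestinal gastric cancer (69)	intestinal_type
sahasrabudhe_2017	CG-008	PALB2	c.1240C>T	Stop-site gain	European	Diffuse gastric cancer (48)	
sahasrabudhe_2017	GM037589	PALB2	c.1240C>T	Stop-site gain	European	Gastric cancer (46)	
sahasrabudhe_2017	CG-05	PALB2	c.3201+1G>T	Splice-site variant	European	Diffuse gastric cancer (50)	
sahasrabudhe_2017	CG-039	PALB2	c.1882_1890delAAGTCCTGC	In-frame deletion	European	Diffuse gastric cancer (47)	
sahasrabudhe_2017	CG-028	PALB2	c.1882_1890delAAGTCCTGC	In-frame deletion	Latin American	Intestinal gastric cancer (81)	
sahasrabudhe_2017	3CG-103	PALB2	c.2753C>A	Missense	Latin American	Mixed gastric cancer (79)	
discovery_wes	GST_172_301	PALB2	c.757_758TAG>T	fs deletion	European	Diffuse gastric cancer (55)	
teixeira_unpublished	GM048157	PALB2	c.1438A>T	Stop-site gain	European	Diffuse gastric cancer (56)	search_criteria
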