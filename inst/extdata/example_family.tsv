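famid	id	father_id	mother_id	sex	birth_year	censor_age	prostate_dx_age	breast_dx_age	ovarian_dx_age	detection	proband	arm	brca2_test	brca1_test	hoxb13_test	pgs
example	father	NA	NA	M	1935	68	68	NA	NA	not_applicable	FALSE	none	untested	untested	untested	NA
example	mother	NA	NA	F	1937	NA	NA	NA	NA	not_applicable	FALSE	none	untested	untested	untested	NA
example	consultand	father	mother	M	1965	45	NA	NA	NA	not_applicable	TRUE	none	untested	untested	untested	NA
example	brother1	father	mother	M	1963	58	55	NA	NA	not_applicable	FALSE	none	untested	untested	untested	NA
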