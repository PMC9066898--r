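mirna	study	location	trend
miR-122-5p	Gillet 2019	Placental exosomes	+
miR-132-3p	Gillet 2019	Placental exosomes	+
miR-1323	Gillet 2019	Placental exosomes	+
miR-136-5p	Gillet 2019	Placental exosomes	+
miR-182-3p	Gillet 2019	Placental exosomes	+
miR-210-3p	Gillet 2019	Placental exosomes	+
miR-29a-3p	Gillet 2019	Placental exosomes	+
miR-29b-3p	Gillet 2019	Placental exosomes	+
miR-342-3p	Gillet 2019	Placental exosomes	+
miR-520h	Gillet 2019	Placental exosomes	+
miR-138-5p	Ding 2018	Placenta	-
miR-202-5p	Ding 2018	Placenta	+
miR-210-5p	Ding 2018	Placenta	-
miR-3158-5p	Ding 2018	Placenta	-
miR-4732-3p	Ding 2018	Placenta	-
miR-125a-3p	Nair 2018	Placenta, placental-derived exosomes, circulating exosomes and skeletal muscle	+
miR-99b-5p	Nair 2018	Placenta, placental-derived exosomes, circulating exosomes and skeletal muscle	+
miR-197-3p	Nair 2018	Placenta, placental-derived exosomes, circulating exosomes and skeletal muscle	+
miR-22-3p	Nair 2018	Placenta, placental-derived exosomes, circulating exosomes and skeletal muscle	+
miR-224-5p	Nair 2018	Placenta, placental-derived exosomes, circulating exosomes and skeletal muscle	+
miR-584-5p	Nair 2018	Placenta, placental-derived exosomes	+
miR-186-5p	Nair 2018	Placenta, placental-derived exosomes	+
miR-433-3p	Nair 2018	Placenta, placental-derived exosomes	+
miR-423-3p	Nair 2018	Placenta, placental-derived exosomes	+
miR-208a-3p	Nair 2018	Placenta, placental-derived exosomes	-
miR-335-5p	Nair 2018	Placenta, placental-derived exosomes	-
miR-451a	Nair 2018	Placenta, placental-derived exosomes	-
miR-145-3p	Nair 2018	Placenta, placental-derived exosomes	-
miR-369-3p	Nair 2018	Placenta, placental-derived exosomes	-
miR-483-3p	Nair 2018	Placenta, placental-derived exosomes	-
miR-203a-3b	Nair 2018	Placenta, placental-derived exosomes	-
miR-574-3p	Nair 2018	Placenta, placental-derived exosomes	-
miR-144-3p	Nair 2018	Placenta, placental-derived exosomes	-
miR-6795-5p	Nair 2018	Placenta, placental-derived exosomes	-
miR-550a-3-3p	Nair 2018	Placenta, placental-derived exosomes	-
miR-411-5p	Nair 2018	Placenta, placental-derived exosomes	-
miR-140-3p	Nair 2018	Placenta, placental-derived exosomes	-
MIR96	Li 2018	Placenta	-
miR-503	Xu 2017	Placenta	+
miR-143	Muralimanoharan 2016	Placenta	-
miR-508-3p	Li 2015	Placenta	+
miR-27a	Li 2015	Placenta	-
miR-9	Li 2015	Placenta	-
miR-92a	Li 2015	Placenta	-
miR-30d	Li 2015	Placenta	-
miR-362-5p	Li 2015	Placenta	-
miR-502-5p	Li 2015	Placenta	-
miR-33a	Li 2015	Placenta	-
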