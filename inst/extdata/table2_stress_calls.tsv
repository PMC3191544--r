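gene	cold	salt	dry
CsWRKY2	+	+	+
CsWRKY4	+	nc	nc
CsWRKY5	nc	nc	nc
CsWRKY6	nc	nc	nc
CsWRKY7	nc	nc	nc
CsWRKY8	nc	nc	nc
CsWRKY9	nc	nc	nc
CsWRKY12	nc	nc	nc
CsWRKY13	nc	nc	nc
CsWRKY14	nc	+	+
CsWRKY15	nc	nc	nc
CsWRKY17	nc	nc	nc
CsWRKY18	++	+	++
CsWRKY19	nc	nc	nc
CsWRKY20	nc	nc	nc
CsWRKY21	++	++	++
CsWRKY22	nc	nc	nc
CsWRKY23	+	-	nc
CsWRKY24	nc	nc	nc
CsWRKY25	++	nc	nc
CsWRKY26	nc	nc	nc
CsWRKY27	nc	nc	nc
CsWRKY28	-	nc	nc
CsWRKY31	nc	nc	nc
CsWRKY32	nc	nc	nc
CsWRKY33	+	nc	nc
CsWRKY34	nc	nc	nc
CsWRKY35	nc	nc	nc
CsWRKY36	+	nc	nc
CsWRKY37	nc	nc	nc
CsWRKY38	nc	nc	nc
CsWRKY39	nc	+	+
CsWRKY40	++	++	++
CsWRKY41	nc	+	nc
CsWRKY42	nc	+	nc
CsWRKY43	nc	+	+
CsWRKY44	nc	+	+
CsWRKY46	+	++	+
CsWRKY47	nc	nc	nc
CsWRKY49	nc	nc	nc
CsWRKY50	nc	nc	nc
CsWRKY51	nc	nc	nc
CsWRKY52	nc	+	+
CsWRKY53	-	nc	+
CsWRKY54	nc	+	+
CsWRKY55	-	nc	++
CsWRKY56	nc	+	+
CsWRKY57	++	nc	+
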