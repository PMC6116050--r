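# forktrap map: MG1655 length_bp=4641652
MG1655	3925860	3925861	origin:oriC	1	+
MG1655	2738575	2738576	origin:oriX	1	+
MG1655	3550864	3550865	origin:oriY	0	+
MG1655	343482	343483	origin:oriZ	1	+
MG1655	1341427	1341428	ter:terA	0	-
MG1655	1682002	1682003	ter:terB	0	+
MG1655	1608788	1608789	ter:terC	0	+
MG1655	1278898	1278899	ter:terD	0	-
MG1655	1245961	1245962	ter:terE	0	-
MG1655	2312906	2312907	ter:terF	0	+
MG1655	2391360	2391361	ter:terG	0	+
MG1655	583532	583533	ter:terH	0	-
MG1655	1096904	1096905	ter:terI	0	-
MG1655	2520000	2520001	ter:terJ	0	+
MG1655	4035153	4040906	txn:rrnA	1	+
MG1655	4166659	4172057	txn:rrnB	1	+
MG1655	3941808	3947213	txn:rrnC	1	+
MG1655	3423194	3428772	txn:rrnD	1	-
MG1655	4208147	4213594	txn:rrnE	1	+
MG1655	2729616	2735184	txn:rrnG	1	-
MG1655	223771	229278	txn:rrnH	1	+
MG1655	3436000	3467000	txn:GRP	1	-
MG1655	575000	576195	is:IS5_575	1195	+
MG1655	1394000	1395195	is:IS5_1394	1195	+
MG1655	2288000	2289195	is:IS5_2288	1195	+
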