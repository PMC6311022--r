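individual_id	population	Du215_a1	Du215_a2	Du281_a1	Du281_a2	Du323_a1	Du323_a2	Du47G_a1	Du47G_a2
Dsegh_01	Dsegh	2	3	2	4	2	3	1	5
Dsegh_02	Dsegh	2	3	2	4	2	3	1	5
Dsegh_03	Dsegh	1	3	2	4	2	3	5	5
Harich_01	Harich	2	3	2	4	2	3	2	4
Harich_02	Harich	2	3	2	4	2	3	2	4
Harich_03	Harich	2	3	2	4	2	3	2	4
Harich_04	Harich	2	3	2	4	2	3	2	4
Harich_05	Harich	2	3	2	4	2	3	2	4
Harich_06	Harich	2	3	2	4	2	3	2	4
Harich_07	Harich	2	3	2	4	2	3	2	4
Harich_08	Harich	2	3	2	4	2	3	2	4
Harich_09	Harich	2	3	2	4	2	3	2	4
Harich_10	Harich	2	3	2	4	2	3	2	4
Harich_11	Harich	2	3	2	4	2	3	2	4
Harich_12	Harich	2	3	2	4	2	3	2	4
Harich_13	Harich	2	3	2	4	2	3	1	5
Harich_14	Harich	2	3	2	4	2	3	1	4
Harich_15	Harich	2	3	2	4	2	3	1	4
Harich_16	Harich	2	3	2	4	2	3	2	3
Harich_17	Harich	2	3	2	4	2	3	2	3
Harich_18	Harich	2	3	2	4	2	3	6	7
Kuchak_01	Kuchak	2	3	2	4	2	3	2	5
Kuchak_02	Kuchak	2	3	2	4	2	3	2	5
Kuchak_03	Kuchak	2	3	2	4	2	3	2	5
Kuchak_04	Kuchak	2	3	2	4	2	3	2	5
Kuchak_05	Kuchak	2	3	2	4	2	3	2	5
Kuchak_06	Kuchak	2	3	2	4	2	3	2	5
Kuchak_07	Kuchak	2	3	1	4	2	3	2	5
Sevan_01	Sevan	2	3	2	4	2	3	2	5
Lchashen_01	Lchashen	2	3	2	4	2	3	2	5
Meghradzor_01	Meghradzor	2	3	2	4	2	3	2	5
Meghradzor_02	Meghradzor	2	3	2	4	2	3	2	5
Meghradzor_03	Meghradzor	2	3	2	4	1	3	2	5
Meghradzor_04	Meghradzor	2	3	2	4	1	3	2	5
Meghradzor_05	Meghradzor	2	3	2	4	1	3	2	5
Meghradzor_06	Meghradzor	2	3	2	4	1	3	2	5
Meghradzor_07	Meghradzor	2	3	2	4	1	3	2	5
Meghradzor_08	Meghradzor	2	3	2	4	1	3	2	5
Meghradzor_09	Meghradzor	2	3	2	4	1	3	2	5
Medvedgora_01	Medved-gora	2	3	2	4	2	3	2	5
Medvedgora_02	Medved-gora	2	3	2	4	2	3	2	5
Medvedgora_03	Medved-gora	2	3	2	4	2	3	2	5
Medvedgora_04	Medved-gora	2	3	2	4	2	3	2	5
Medvedgora_05	Medved-gora	2	3	2	4	2	3	2	5
Medvedgora_06	Medved-gora	2	3	2	4	2	3	2	5
Medvedgora_07	Medved-gora	2	3	2	4	2	3	2	5
Medvedgora_08	Medved-gora	2	3	2	4	2	3	2	5
Medvedgora_09	Medved-gora	2	3	2	4	2	3	2	5
Medvedgora_10	Medved-gora	2	3	2	4	2	3	2	5
Medvedgora_11	Medved-gora	2	3	2	4	2	3	1	5
Medvedgora_12	Medved-gora	2	3	2	4	2	3	1	5
Dilijan_01	Dilijan	2	3	2	4	2	3	2	5
Dilijan_02	Dilijan	2	3	2	4	2	3	2	5
Dilijan_03	Dilijan	2	3	2	4	2	3	2	5
Dilijan_04	Dilijan	2	3	2	4	2	3	2	3
PushkinPass_01	Pushkin-Pass	2	3	2	4	2	3	2	5
PushkinPass_02	Pushkin-Pass	2	3	2	4	2	3	2	5
PushkinPass_03	Pushkin-Pass	2	3	2	4	2	3	1	5
PushkinPass_04	Pushkin-Pass	2	3	2	4	2	3	1	5
PushkinPass_05	Pushkin-Pass	2	3	2	4	2	3	1	5
PushkinPass_06	Pushkin-Pass	2	3	2	4	2	3	1	5
PushkinPass_07	Pushkin-Pass	2	3	2	4	2	3	1	5
DilijanSemyonovka_01	Dilijan-Semyonovka	2	3	2	4	2	3	2	5
DilijanSemyonovka_02	Dilijan-Semyonovka	2	3	2	3	2	3	2	5
DilijanSemyonovka_03	Dilijan-Semyonovka	2	3	2	3	2	3	2	5
DilijanSemyonovka_04	Dilijan-Semyonovka	2	3	2	3	2	3	2	5
DilijanSemyonovka_05	Dilijan-Semyonovka	2	3	2	3	2	3	2	5
DilijanSemyonovka_06	Dilijan-Semyonovka	2	3	2	3	2	3	2	5
DilijanSemyonovka_07	Dilijan-Semyonovka	2	3	2	3	2	3	5	5
DilijanSemyonovka_08	Dilijan-Semyonovka	2	3	2	3	2	3	5	5
Sotk_01	Sotk	2	3	2	4	2	3	2	5
Sotk_02	Sotk	2	3	2	4	2	3	1	4
Sotk_03	Sotk	2	3	2	4	2	3	1	4
Stepanavan_01	Stepanavan	2	3	2	4	2	3	2	5
Stepanavan_02	Stepanavan	2	3	2	4	2	3	2	5
Stepanavan_03	Stepanavan	2	3	2	4	2	3	2	5
Stepanavan_04	Stepanavan	2	3	2	4	2	3	2	5
Stepanavan_05	Stepanavan	2	3	2	4	2	3	2	5
Stepanavan_06	Stepanavan	2	3	2	4	2	3	2	4
Stepanavan_07	Stepanavan	2	3	2	4	2	3	1	4
Stepanavan_08	Stepanavan	2	3	1	4	2	3	1	5
Stepanavan_09	Stepanavan	2	3	2	4	2	3	5	5
Artavaz_01	Artavaz	2	3	2	4	2	3	2	5
Artavaz_02	Artavaz	2	3	2	4	2	3	2	5
Artavaz_03	Artavaz	2	3	2	4	2	3	2	5
Artavaz_04	Artavaz	2	3	2	4	2	3	2	5
Artavaz_05	Artavaz	2	3	2	4	2	3	2	5
Artavaz_06	Artavaz	2	3	2	4	2	3	2	5
Artavaz_07	Artavaz	2	3	2	4	2	3	2	5
Artavaz_08	Artavaz	2	3	2	4	2	3	2	5
Artavaz_09	Artavaz	2	3	2	4	2	3	2	5
Artavaz_10	Artavaz	2	3	2	4	2	3	2	5
Artavaz_11	Artavaz	2	3	2	4	2	3	2	5
Artavaz_12	Artavaz	2	3	2	4	2	3	2	5
Artavaz_13	Artavaz	2	3	2	4	2	3	2	5
Artavaz_14	Artavaz	2	3	2	4	2	3	2	5
Artavaz_15	Artavaz	2	3	2	4	2	3	2	5
Artavaz_16	Artavaz	2	3	2	4	2	3	2	5
Artavaz_17	Artavaz	2	3	2	4	2	3	2	5
Artavaz_18	Artavaz	2	3	2	4	2	3	2	5
Artavaz_19	Artavaz	2	3	2	4	2	3	2	5
Artavaz_20	Artavaz	2	3	2	4	2	3	2	5
Artavaz_21	Artavaz	2	3	2	4	2	3	2	5
Tezh_01	Tezh	2	3	2	4	2	3	2	5
Tezh_02	Tezh	2	3	2	4	2	3	2	5
Tezh_03	Tezh	2	3	2	4	2	3	2	5
Tezh_04	Tezh	2	3	2	4	2	3	2	5
Tezh_05	Tezh	2	3	2	4	2	3	2	5
Tezh_06	Tezh	2	3	2	4	2	3	2	5
Tezh_07	Tezh	2	3	2	4	2	3	2	5
Tezh_08	Tezh	2	3	2	4	2	3	2	5
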