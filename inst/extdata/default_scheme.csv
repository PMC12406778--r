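index,label,domain_tag,origin
1,Mother too busy,demand,original_option
2,Child was sick,demand,original_option
3,Vaccination site too far,community_access,original_option
4,Fear of side effects,demand,original_option
5,No vaccine available at site,supply,original_option
6,Health worker absent,supply,original_option
7,Did not know where to go,knowledge,original_option
8,Did not know vaccines were needed,knowledge,original_option
9,Wrong time for vaccination session,supply,original_option
10,Long wait at the site,supply,original_option
11,Family refusal,demand,original_option
12,Religious beliefs,demand,original_option
13,Mother unwell after delivery,demand,original_option
14,Lost the vaccination card,demand,original_option
15,Cost of vaccination services,community_access,original_option
16,Insecurity in the area,community_access,original_option
17,Epidemic disruption,supply,original_option
18,Child too young,knowledge,original_option
19,Distrust of health services,demand,original_option
20,No transport available,community_access,original_option
21,Father refused,demand,original_option
22,Other family obligations,demand,original_option
23,"Travel, move, and displacement",community_access,added_category
24,Negligence,demand,added_category
25,Vaccine schedule in progress,knowledge,added_category
26,Health worker strike,supply,added_category
27,Working in the field,community_access,added_category
28,Rumors,demand,added_category
29,Mother absent,community_access,added_category
30,Child born at home,community_access,added_category
31,Forgot the appointment,demand,added_category
32,Not informed of the session,knowledge,added_category
33,Bad weather,community_access,added_category
34,River or road impassable,community_access,added_category
35,Health facility closed,supply,added_category
36,Vaccination postponed by staff,supply,added_category
37,Caregiver illness,demand,added_category
38,Caring for twins or many children,demand,added_category
39,Moved to another health area,community_access,added_category
40,Waiting for a campaign,knowledge,added_category
41,Child refused or cried,demand,added_category
42,Family conflict,demand,added_category
43,No reason given,other,added_category
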